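test_that("top-k neighbors rank by similarity with index tie-breaks and caps", {
  K <- rbind(c(1, 0.4, 0.2, 0.2),
             c(0.4, 1, 0.1, 0.3),
             c(0.2, 0.1, 1, 0.5),
             c(0.2, 0.3, 0.5, 1))
  expect_equal(top_k_neighbors(K, 1, 3), c(2L, 3L, 4L))  # tie 3 vs 4
  expect_equal(top_k_neighbors(K, 1, 2), c(2L, 3L))
  expect_equal(top_k_neighbors(diag(3), 1, 3), c(2L, 3L))  # capped at N-1
  KM <- gip_kernel(worked_toy()$adjacency, "microbe")
  expect_equal(top_k_neighbors(KM, 1, 3), c(2L, 3L, 4L))
})

test_that("neighbor ratios normalize similarities to a unit sum", {
  K <- matrix(1, 4, 4)
  expect_equal(unname(neighbor_ratio(K, 1, c(2, 3, 4))), rep(1 / 3, 3))
  expect_equal(unname(neighbor_ratio(K, 1, 2)), 1)
  KM <- gip_kernel(worked_toy()$adjacency, "microbe")
  r <- neighbor_ratio(KM, 1, c(2, 3, 4))
  expect_equal(sum(r), 1)
  expect_equal(unname(r), c(0.5267, 0.2367, 0.2367), tolerance = 1e-4)
  expect_error(neighbor_ratio(K, 1, integer()), "empty")
})

test_that("the worked toy recommends disease d2 to microbe m1", {
  ds <- worked_toy()
  KM <- gip_kernel(ds$adjacency, "microbe")
  tr <- recommend_one(ds$adjacency, KM, 1, "microbe", 3)
  expect_equal(tr$neighbor_set, c(2L, 3L, 4L))
  expect_equal(unname(tr$candidate_targets), 1:3)
  expect_equal(tr$chosen, 2L)
  # scores agree with the independent enumerator
  orc <- oracle_recommend(ds$adjacency, KM, 1, "microbe", 3)
  expect_equal(unname(tr$scores), unname(orc$scores), tolerance = 1e-12)
  expect_equal(tr$chosen, orc$chosen)
})

test_that("isolated subjects and single candidates are handled", {
  # block-diagonal: microbes 3,4 only touch disease 2; m1's neighbors all
  # lie in its own block -> candidate set is just d1
  A <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  KM <- gip_kernel(A, "microbe")
  tr <- recommend_one(A, KM, 1, "microbe", 1)
  expect_equal(unname(tr$candidate_targets), 1L)
  expect_equal(tr$chosen, 1L)
  # a subject with no associated neighbor diseases chooses nothing
  A2 <- rbind(c(1L, 0L), c(0L, 0L))
  tr2 <- recommend_one(A2, gip_kernel(A2, "microbe"), 1, "microbe", 3)
  expect_true(is.na(tr2$chosen))
  # cross-pair toy: each microbe's single neighbor leads to the other disease
  I2 <- diag(2); storage.mode(I2) <- "integer"
  tr3 <- recommend_one(I2, gip_kernel(I2, "microbe"), 1, "microbe", 3)
  expect_equal(tr3$chosen, 2L)
})

test_that("augmentation adds at most one association per subject, monotonically", {
  I2 <- diag(2); storage.mode(I2) <- "integer"
  KM <- gip_kernel(I2, "microbe"); KD <- gip_kernel(I2, "disease")
  aug <- augment_adjacency(I2, KM, KD, 3)
  expect_equal(aug$A_m, matrix(1L, 2, 2))
  expect_equal(aug$A_d, matrix(1L, 2, 2))
  # saturated adjacency is a fixed point
  ones <- matrix(1L, 3, 4)
  aug2 <- augment_adjacency(ones, gip_kernel(ones, "microbe"),
                            gip_kernel(ones, "disease"), 3)
  expect_equal(aug2$A_m, ones)
  expect_equal(aug2$A_d, ones)
  set.seed(21)
  for (rep in 1:10) {
    A <- rand_adjacency(sample(2:5, 1), sample(2:7, 1), 0.35)
    aug3 <- augment_adjacency(A, gip_kernel(A, "microbe"),
                              gip_kernel(A, "disease"), 3)
    expect_true(all(aug3$A_m >= A))
    expect_true(all(aug3$A_d >= A))
    expect_lte(sum(aug3$A_m) - sum(A), ncol(A))
    expect_lte(sum(aug3$A_d) - sum(A), nrow(A))
  }
})

test_that("recommendations match the brute-force enumerator on random networks", {
  set.seed(17)
  for (rep in 1:50) {
    nd <- sample(2:5, 1); nm <- sample(2:7, 1)
    A <- rand_adjacency(nd, nm, stats::runif(1, 0.15, 0.5), min_nnz = 1L)
    KM <- gip_kernel(A, "microbe")
    KD <- gip_kernel(A, "disease")
    k <- sample(1:3, 1)
    for (j in seq_len(nm)) {
      tr <- recommend_one(A, KM, j, "microbe", k)
      orc <- oracle_recommend(A, KM, j, "microbe", k)
      expect_equal(tr$chosen, orc$chosen)
      expect_equal(unname(tr$scores), unname(orc$scores), tolerance = 1e-12)
    }
    for (i in seq_len(nd)) {
      tr <- recommend_one(A, KD, i, "disease", k)
      orc <- oracle_recommend(A, KD, i, "disease", k)
      expect_equal(tr$chosen, orc$chosen)
      expect_equal(unname(tr$scores), unname(orc$scores), tolerance = 1e-12)
    }
  }
})

test_that("augmentation is deterministic", {
  set.seed(2)
  A <- rand_adjacency(4, 6, 0.3)
  KM <- gip_kernel(A, "microbe"); KD <- gip_kernel(A, "disease")
  a1 <- augment_adjacency(A, KM, KD, 3)
  a2 <- augment_adjacency(A, KM, KD, 3)
  expect_identical(a1$A_m, a2$A_m)
  expect_identical(a1$A_d, a2$A_d)
})
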