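test_that("edge-list reading collapses duplicates and orders by first appearance", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tm1", "d2\tm2", "d1\tm1"), f)
  ds <- read_associations(f)
  expect_equal(ds$disease_names, c("d1", "d2"))
  expect_equal(ds$microbe_names, c("m1", "m2"))
  expect_equal(sum(ds$adjacency), 2L)
  expect_equal(unname(ds$adjacency), rbind(c(1L, 0L), c(0L, 1L)))
})

test_that("a single-pair file reads to a 1x1 adjacency without error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("d1\tm1", f)
  ds <- read_associations(f)
  expect_equal(unname(ds$adjacency), matrix(1L, 1, 1))
})

test_that("comments and blank lines are skipped, names trimmed but not case-folded", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment", "", " asthma \tBacteroides\tPMID:1",
               "asthma\tbacteroides"), f)
  ds <- read_associations(f)
  expect_equal(ds$disease_names, "asthma")
  expect_equal(ds$microbe_names, c("Bacteroides", "bacteroides"))
  expect_equal(sum(ds$adjacency), 2L)
})

test_that("malformed input raises informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# only a comment"), f)
  expect_error(read_associations(f), "no associations")
  writeLines(c("d1\tm1", "orphan-field"), f)
  expect_error(read_associations(f), "line 2")
})

test_that("a 450-pair catalog over 39 diseases and 292 microbes reads back exactly", {
  set.seed(42)
  nd <- 39L; nm <- 292L
  # every disease and microbe appears at least once, 450 unique pairs total
  d_of_m <- sample(c(seq_len(nd), sample.int(nd, nm - nd, replace = TRUE)))
  pairs <- cbind(d_of_m, seq_len(nm))
  pool <- which(is.na(match(seq_len(nd * nm),
                            (pairs[, 2] - 1L) * nd + pairs[, 1])))
  extra <- sample(pool, 450L - nm)
  pairs <- rbind(pairs, cbind((extra - 1L) %% nd + 1L, (extra - 1L) %/% nd + 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("disease_%02d\tmicrobe_%03d", pairs[, 1], pairs[, 2]), f)
  ds <- read_associations(f)
  expect_equal(dim(ds$adjacency), c(39L, 292L))
  expect_equal(sum(ds$adjacency), 450L)
})

test_that("read-write-read round-trips preserve adjacency and name ordering", {
  set.seed(7)
  for (rep in 1:25) {
    nd <- sample(2:6, 1); nm <- sample(2:8, 1)
    A <- rand_adjacency(nd, nm, p = 0.4)
    edges <- which(A == 1L, arr.ind = TRUE)
    edges <- edges[sample(nrow(edges)), , drop = FALSE]  # random line order
    f1 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(sprintf("D%d\tM%d", edges[, 1], edges[, 2]), f1)
    d1 <- read_associations(f1)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_associations(d1, f2, header = c("round-trip test"))
    d2 <- read_associations(f2)
    expect_identical(d2$disease_names, d1$disease_names)
    expect_identical(d2$microbe_names, d1$microbe_names)
    expect_identical(d2$adjacency, d1$adjacency)
  }
})

test_that("rankings are sorted by score with deterministic index tie-breaks", {
  ds <- association_dataset(rbind(c(1L, 0L), c(0L, 1L)), c("d1", "d2"),
                            c("m1", "m2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_rankings(rbind(c(.9, .1), c(.2, .8)), ds, f)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$score[1], 0.9)
  expect_equal(tab$rank, 1:4)
  # only unknown pairs
  tab2 <- write_rankings(rbind(c(.9, .1), c(.2, .8)), ds, f,
                         only_unknown = TRUE)
  expect_equal(nrow(tab2), 2L)
  expect_setequal(paste(tab2$disease, tab2$microbe),
                  c("d1 m2", "d2 m1"))
  # all-equal scores fall back to index order
  tab3 <- write_rankings(matrix(0.5, 2, 2), ds, f)
  expect_equal(paste(tab3$disease, tab3$microbe),
               c("d1 m1", "d1 m2", "d2 m1", "d2 m2"))
  # written file parses and matches
  parsed <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(parsed), 4L)
})

test_that("dataset constructor validates its invariants", {
  expect_error(association_dataset(matrix(2, 1, 1), "d", "m"), "0/1")
  expect_error(association_dataset(matrix(0, 2, 2), c("d", "d"), c("a", "b")),
               "duplicate")
  expect_error(association_dataset(matrix(0, 2, 2), "d", c("a", "b")),
               "dimensions")
})
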