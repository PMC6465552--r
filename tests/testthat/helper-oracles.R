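# Independent brute-force oracles. These deliberately share no code with the
# package: double loops, repeated max-selection and explicit set enumeration
# only, so they can stand as a second route against the vectorized
# implementation.

oracle_gip_kernel <- function(A, axis, gamma_prime = 1) {
  profiles <- if (axis == "microbe") {
    lapply(seq_len(ncol(A)), function(j) A[, j])
  } else {
    lapply(seq_len(nrow(A)), function(i) A[i, ])
  }
  n <- length(profiles)
  gamma <- gamma_prime / mean(vapply(profiles, function(p) sum(p^2), numeric(1)))
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-gamma * sum((profiles[[i]] - profiles[[j]])^2))
    }
  }
  K
}

# top-k by repeated max selection; ties to the lowest index because the
# scan runs in ascending index order with a strict improvement test
oracle_top_k <- function(K, i, k) {
  n <- nrow(K)
  sel <- integer(0)
  while (length(sel) < min(k, n - 1L)) {
    best <- NA_integer_
    bestv <- -Inf
    for (j in seq_len(n)) {
      if (j == i || j %in% sel) next
      if (K[i, j] > bestv) {
        bestv <- K[i, j]
        best <- j
      }
    }
    sel <- c(sel, best)
  }
  sel
}

# Literal enumeration of the one-sided recommendation: neighbor set, ratio,
# candidate set, first-order sum over associated neighbors, second-order sum
# over each neighbor's own neighbor set restricted to nodes associated with
# the candidate.
oracle_recommend <- function(A, K, subject, axis, k) {
  B <- if (axis == "microbe") A else t(A)
  if (ncol(B) < 2L) return(list(chosen = NA_integer_, scores = numeric()))
  Q1 <- oracle_top_k(K, subject, k)
  ratio <- function(i, nbs, j) K[i, j] / sum(K[i, nbs])
  targets <- integer(0)
  for (t in seq_len(nrow(B))) {
    for (m in Q1) if (B[t, m] == 1) targets <- c(targets, t)
  }
  targets <- sort(unique(targets))
  if (length(targets) == 0L) return(list(chosen = NA_integer_, scores = numeric()))
  DS <- numeric(length(targets))
  for (ti in seq_along(targets)) {
    t <- targets[ti]
    s <- 0
    for (m in Q1) if (B[t, m] == 1) s <- s + ratio(subject, Q1, m)
    for (p in Q1) {
      Qp1 <- oracle_top_k(K, p, k)
      for (q in Qp1) {
        if (B[t, q] == 1) s <- s + ratio(subject, Q1, p) * ratio(p, Qp1, q)
      }
    }
    DS[ti] <- s
  }
  best <- targets[1L]
  bestv <- DS[1L]
  for (ti in seq_along(targets)) {
    if (DS[ti] > bestv) {
      bestv <- DS[ti]
      best <- targets[ti]
    }
  }
  list(chosen = best, scores = stats::setNames(DS, targets))
}

# explicit path-sum for one weighted propagation step
oracle_propagate2 <- function(S, w) {
  n <- nrow(S)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + S[i, k] * w[k] * S[k, j]
      out[i, j] <- acc
    }
  }
  out
}

# threshold-sweep ROC with trapezoidal integration (independent AUC route)
oracle_trapezoid_auc <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  fpr <- c(0, vapply(th, function(t) mean(neg >= t), numeric(1)))
  tpr <- c(0, vapply(th, function(t) mean(pos >= t), numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# quadratic-time pairwise AUC (Mann-Whitney, ties half)
oracle_pairwise_auc <- function(pos, neg) {
  acc <- 0
  for (p in pos) {
    for (n in neg) acc <- acc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

# random binary adjacency with at least `min_nnz` associations
rand_adjacency <- function(nd, nm, p = 0.3, min_nnz = 2L) {
  repeat {
    A <- matrix(as.integer(stats::runif(nd * nm) < p), nd, nm)
    if (sum(A) >= min_nnz) return(A)
  }
}

rand_dataset <- function(nd, nm, p = 0.3, min_nnz = 2L) {
  association_dataset(rand_adjacency(nd, nm, p, min_nnz),
                      paste0("d", seq_len(nd)), paste0("m", seq_len(nm)))
}
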