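#' Top-k most similar neighbors of a node
#'
#' Returns the indices of the `k` nodes other than `i` with the largest
#' similarity to `i`, in descending similarity order. Ties are broken by
#' ascending index; `k` is capped at `N - 1`.
#'
#' @param K_mat square similarity matrix.
#' @param i node index.
#' @param k number of neighbors requested (>= 1).
#' @return Integer vector of neighbor indices.
#' @export
top_k_neighbors <- function(K_mat, i, k) {
  stopifnot(k >= 1)
  n <- nrow(K_mat)
  vals <- K_mat[i, ]
  vals[i] <- -Inf
  ord <- order(vals, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  ord[seq_len(min(k, n - 1L))]
}

#' Recommendation weight of each neighbor
#'
#' Normalizes the similarities from node `i` to its neighbor set so they sum
#' to one: `R(i, j) = K[i, j] / sum_k K[i, k]` over the neighbors.
#'
#' @param K_mat square similarity matrix.
#' @param i subject node index.
#' @param neighbors nonempty integer vector of neighbor indices.
#' @return Numeric vector of ratios, named by neighbor index, summing to 1.
#' @export
neighbor_ratio <- function(K_mat, i, neighbors) {
  if (length(neighbors) == 0L) stop("empty neighbor set")
  s <- sum(K_mat[i, neighbors])
  if (s <= 0) stop("zero denominator in neighbor ratio")
  stats::setNames(K_mat[i, neighbors] / s, neighbors)
}

#' Score and choose one recommended partner for a node
#'
#' Implements one side of the bidirectional recommendation. For a subject
#' microbe (resp. disease), the candidate targets are the diseases
#' (microbes) associated with at least one of the subject's top-k most
#' similar neighbors. A candidate's first-order score sums the
#' [neighbor_ratio()] weights of the neighbors it is associated with; a
#' second-order term adds, for every neighbor `p` and every node `q` in
#' `p`'s own top-k set that is associated with the candidate, the product
#' `R(subject, p) * R(p, q)`, boosting candidates reachable through two
#' similarity hops. The highest-scoring candidate is chosen (ties by
#' ascending index); with no candidates the choice is `NA`.
#'
#' @param A binary adjacency (diseases x microbes).
#' @param K_mat similarity kernel on the subject's axis (raw, unnormalized).
#' @param subject node index on `axis`.
#' @param axis `"microbe"` (recommend a disease) or `"disease"` (recommend a
#'   microbe).
#' @param k neighborhood size (default 3).
#' @return A list of class `recommendation_trace` with elements `subject`,
#'   `axis`, `neighbor_set`, `neighbor_ratios`, `candidate_targets`,
#'   `second_order_sets`, `scores` (named by candidate index) and `chosen`
#'   (target index or `NA`).
#' @export
recommend_one <- function(A, K_mat, subject, axis = c("microbe", "disease"),
                          k = 3) {
  axis <- match.arg(axis)
  A <- as.matrix(A)
  # B: candidate-target rows x subject-axis columns
  B <- if (axis == "microbe") A else t(A)
  n_peer <- ncol(B)
  stopifnot(subject >= 1, subject <= n_peer,
            nrow(K_mat) == n_peer, ncol(K_mat) == n_peer)
  trace <- structure(
    list(subject = subject, axis = axis, neighbor_set = integer(),
         neighbor_ratios = numeric(), candidate_targets = integer(),
         second_order_sets = list(), scores = numeric(), chosen = NA_integer_),
    class = "recommendation_trace")
  if (n_peer < 2L) return(trace)
  nb <- top_k_neighbors(K_mat, subject, k)
  r <- neighbor_ratio(K_mat, subject, nb)
  trace$neighbor_set <- nb
  trace$neighbor_ratios <- r
  assoc <- B[, nb, drop = FALSE] == 1L
  candidates <- which(rowSums(assoc) > 0L)
  trace$candidate_targets <- candidates
  if (length(candidates) == 0L) return(trace)
  scores <- rowSums(assoc * rep(r, each = nrow(B)))[candidates]
  second <- vector("list", length(nb))
  names(second) <- as.character(nb)
  for (pi in seq_along(nb)) {
    p <- nb[pi]
    nb_p <- top_k_neighbors(K_mat, p, k)
    r_p <- neighbor_ratio(K_mat, p, nb_p)
    second[[pi]] <- list(neighbors = nb_p, ratios = r_p)
    assoc_p <- B[candidates, nb_p, drop = FALSE] == 1L
    scores <- scores + as.vector(assoc_p %*% r_p) * r[pi]
  }
  trace$second_order_sets <- second
  trace$scores <- stats::setNames(scores, candidates)
  trace$chosen <- unname(candidates[order(-scores, candidates)][1L])
  trace
}

#' Densify an adjacency by bidirectional recommendation
#'
#' Applies [recommend_one()] once per microbe (adding its chosen disease to
#' produce `A_m`) and once per disease (adding its chosen microbe to produce
#' `A_d`). Both sides start independently from the same original adjacency,
#' so each side adds at most one association per subject node and never
#' removes one. A recommendation landing on an already-known pair is a no-op.
#'
#' @param A binary adjacency (diseases x microbes).
#' @param KM,KD raw microbe and disease kernels from [gip_kernel()].
#' @param k neighborhood size (default 3).
#' @return A list of class `augmented_associations` with binary matrices
#'   `A_m` and `A_d` and the per-subject `traces`.
#' @export
augment_adjacency <- function(A, KM, KD, k = 3) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  A_m <- A
  A_d <- A
  traces <- vector("list", ncol(A) + nrow(A))
  for (j in seq_len(ncol(A))) {
    tr <- recommend_one(A, KM, j, "microbe", k)
    if (!is.na(tr$chosen)) A_m[tr$chosen, j] <- 1L
    traces[[j]] <- tr
  }
  for (i in seq_len(nrow(A))) {
    tr <- recommend_one(A, KD, i, "disease", k)
    if (!is.na(tr$chosen)) A_d[i, tr$chosen] <- 1L
    traces[[ncol(A) + i]] <- tr
  }
  structure(list(A_m = A_m, A_d = A_d, traces = traces),
            class = "augmented_associations")
}
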