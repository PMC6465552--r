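#' Assemble the bidirectional weighted block matrix
#'
#' Stacks the normalized kernels and the two augmented adjacencies into
#' `S = [[KD*, A_d], [t(A_m), KM*]]`, the directed edge-weight matrix of the
#' bidirectional heterogeneous network (diseases first, then microbes).
#' `S` is asymmetric whenever `A_d != A_m` or the kernels were normalized.
#'
#' @param KD_star normalized disease kernel (N_d x N_d).
#' @param A_d disease-side augmented adjacency (N_d x N_m).
#' @param A_m microbe-side augmented adjacency (N_d x N_m; enters transposed).
#' @param KM_star normalized microbe kernel (N_m x N_m).
#' @return The (N_d + N_m) square matrix `S`.
#' @export
build_S <- function(KD_star, A_d, A_m, KM_star) {
  KD_star <- as.matrix(KD_star); KM_star <- as.matrix(KM_star)
  A_d <- as.matrix(A_d); A_m <- as.matrix(A_m)
  if (nrow(KD_star) != ncol(KD_star) || nrow(KM_star) != ncol(KM_star)) {
    stop("kernel blocks must be square")
  }
  if (!identical(dim(A_d), dim(A_m)) ||
      nrow(A_d) != nrow(KD_star) || ncol(A_d) != nrow(KM_star)) {
    stop("adjacency blocks do not conform with kernel blocks")
  }
  rbind(cbind(KD_star, A_d), cbind(t(A_m), KM_star))
}

#' Propagate the weighted network over walks of length n
#'
#' Starting from `S2 = S %*% W %*% S` (paths of length 2 through a weighted
#' intermediate node), longer propagation follows one of two recursions:
#'
#' * `"squaring"` (default): `S_t = S_{t-1} %*% W %*% S_{t-1}`, the literal
#'   doubling recursion (so `S_3` aggregates 4-edge walks);
#' * `"stepwise"`: `S_t = S_{t-1} %*% W %*% S`, extending walks one edge at
#'   a time (so `S_t` aggregates t-edge walks).
#'
#' Both coincide at the recommended `n = 2`.
#'
#' @param S square non-negative matrix from [build_S()].
#' @param W node-weight diagonal matrix from [node_weights()] (or its
#'   diagonal as a vector).
#' @param n integer number of propagation steps, at least 2.
#' @param variant recursion variant.
#' @return The propagated matrix `S_n`, same dimensions as `S`.
#' @export
propagate <- function(S, W, n, variant = c("squaring", "stepwise")) {
  variant <- match.arg(variant)
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  w <- if (is.matrix(W)) diag(W) else as.numeric(W)
  if (length(w) != nrow(S)) stop("W does not conform with S")
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("n must be an integer >= 2")
  }
  S_t <- S %*% (w * S)
  if (n > 2) {
    for (t in seq.int(3L, n)) {
      S_t <- if (variant == "squaring") S_t %*% (w * S_t) else S_t %*% (w * S)
    }
  }
  S_t
}

#' Fuse the two directed disease-microbe blocks into prediction scores
#'
#' Extracts from the propagated matrix the disease-to-microbe block and the
#' microbe-to-disease block and averages them with equal weight:
#' `A* = (S_n2 + t(S_n3)) / 2`.
#'
#' @param S_n propagated matrix from [propagate()].
#' @param n_d number of diseases (size of the leading block).
#' @return The N_d x N_m fused score matrix.
#' @export
fuse_scores <- function(S_n, n_d) {
  S_n <- as.matrix(S_n)
  stopifnot(n_d >= 1, n_d < nrow(S_n))
  d_idx <- seq_len(n_d)
  (S_n[d_idx, -d_idx, drop = FALSE] +
     t(S_n[-d_idx, d_idx, drop = FALSE])) / 2
}

#' Predict disease-microbe association scores
#'
#' Runs the full pipeline on a dataset: Gaussian interaction-profile kernels
#' on both axes, heterogeneous matrix `P` and node weights `W`, asymmetric
#' kernel normalization, bidirectional recommendation densification of the
#' adjacency, assembly of the bidirectional weighted matrix `S`, propagation
#' over walks of length `n`, and fusion of the two directed blocks.
#'
#' @param dataset an [association_dataset()].
#' @param n propagation steps (default 2, the recommended setting).
#' @param k recommendation neighborhood size (default 3).
#' @param gamma_prime_m,gamma_prime_d kernel bandwidth scales (default 1).
#' @param normalization edge normalization variant, see [normalize_kernel()].
#' @param recursion propagation recursion variant, see [propagate()].
#' @param nz_eps threshold for [nz_row_counts()] (default 0).
#' @return A list of class `md_scores` with the N_d x N_m non-negative
#'   `scores` matrix (dimnames from the dataset) and the resolved `params`.
#' @examples
#' ds <- worked_toy()
#' p <- predict_associations(ds)
#' round(p$scores, 4)
#' @export
predict_associations <- function(dataset, n = 2, k = 3,
                                 gamma_prime_m = 1, gamma_prime_d = 1,
                                 normalization = c("full_denominator",
                                                   "postmultiply"),
                                 recursion = c("squaring", "stepwise"),
                                 nz_eps = 0) {
  stopifnot(inherits(dataset, "association_dataset"))
  normalization <- match.arg(normalization)
  recursion <- match.arg(recursion)
  A <- dataset$adjacency
  kern <- gip_kernel_pair(dataset, gamma_prime_m, gamma_prime_d)
  P <- build_P(kern$KD, A, kern$KM)
  W <- node_weights(P)
  KM_star <- normalize_kernel(kern$KM, normalization, nz_eps)
  KD_star <- normalize_kernel(kern$KD, normalization, nz_eps)
  aug <- augment_adjacency(A, kern$KM, kern$KD, k)
  S <- build_S(KD_star, aug$A_d, aug$A_m, KM_star)
  S_n <- propagate(S, W, n, recursion)
  scores <- fuse_scores(S_n, nrow(A))
  dimnames(scores) <- dimnames(A)
  structure(
    list(scores = scores,
         params = list(n = n, k = k, gamma_prime_m = gamma_prime_m,
                       gamma_prime_d = gamma_prime_d,
                       normalization = normalization, recursion = recursion,
                       nz_eps = nz_eps)),
    class = "md_scores"
  )
}

#' @export
print.md_scores <- function(x, ...) {
  cat(sprintf(
    "md_scores: %d x %d prediction scores (n=%s, k=%s, normalization=%s)\n",
    nrow(x$scores), ncol(x$scores), x$params$n, x$params$k,
    x$params$normalization))
  invisible(x)
}
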