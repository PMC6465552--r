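#' Assemble the heterogeneous block matrix
#'
#' Stacks the disease kernel, the binary adjacency and the microbe kernel
#' into the symmetric block matrix
#' `P = [[KD, A], [t(A), KM]]` over the combined node set
#' (diseases first, then microbes).
#'
#' @param KD disease kernel matrix (N_d x N_d).
#' @param A binary adjacency (N_d x N_m).
#' @param KM microbe kernel matrix (N_m x N_m).
#' @return The (N_d + N_m) square block matrix.
#' @export
build_P <- function(KD, A, KM) {
  KD <- as.matrix(KD); A <- as.matrix(A); KM <- as.matrix(KM)
  if (nrow(KD) != ncol(KD) || nrow(KM) != ncol(KM)) {
    stop("kernel blocks must be square")
  }
  if (nrow(A) != nrow(KD) || ncol(A) != nrow(KM)) {
    stop("adjacency dimensions do not match kernel blocks")
  }
  rbind(cbind(KD, A), cbind(t(A), KM))
}

#' Node-weight diagonal of the heterogeneous network
#'
#' Each node's weight is the reciprocal of the squared Euclidean norm of its
#' row of `P`, i.e. the diagonal of `1 / (P %*% t(P))` read elementwise on
#' the diagonal. Highly connected nodes (long rows) therefore receive small
#' weights, damping their influence during propagation. With unit kernel
#' diagonals every row norm is at least 1, so weights lie in (0, 1].
#'
#' @param P block matrix from [build_P()].
#' @return A diagonal matrix `W` of per-node weights, same node order as `P`.
#' @export
node_weights <- function(P) {
  P <- as.matrix(P)
  sq <- rowSums(P^2)
  if (any(sq == 0)) stop("zero row in P: node weight undefined")
  diag(1 / sq, nrow = length(sq))
}

#' Per-row nonzero counts of a kernel matrix
#'
#' Counts, for each row, the entries strictly greater than `eps`. With the
#' default `eps = 0` a Gaussian kernel has all entries positive, so every
#' count equals the matrix dimension; the threshold only bites when entries
#' underflow or a different similarity source is used.
#'
#' @param K square similarity matrix.
#' @param eps non-negative threshold.
#' @return Integer vector of per-row counts.
#' @export
nz_row_counts <- function(K, eps = 0) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  stopifnot(eps >= 0)
  as.integer(rowSums(K > eps))
}

#' Asymmetric edge normalization of a similarity kernel
#'
#' Rescales a symmetric kernel into the directed edge-weight matrix of the
#' bidirectional network, so that multi-edge paths cannot outscore shorter
#' ones. `K*[i, j]` is the weight of the directed edge from node `i` to node
#' `j`. Two readings of the normalization are provided:
#'
#' * `"full_denominator"` (default): `K*[i, j] = K[i, j] / (colsum_j(K) *
#'   NZ_i)` where `NZ_i` is the [nz_row_counts()] value of row `i`. With an
#'   all-positive kernel (`NZ_i = N`) every column of `K*` then sums to
#'   exactly `1/N`.
#' * `"postmultiply"`: `K*[i, j] = K[i, j] / colsum_j(K) * NZ_i`, i.e. the
#'   column-stochastic kernel scaled up by the row's nonzero count.
#'
#' @param K symmetric similarity matrix with strictly positive column sums.
#' @param variant which grouping of the normalization to apply.
#' @param eps threshold passed to [nz_row_counts()].
#' @return The (generally asymmetric) normalized matrix.
#' @export
normalize_kernel <- function(K, variant = c("full_denominator", "postmultiply"),
                             eps = 0) {
  variant <- match.arg(variant)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  cs <- colSums(K)
  if (any(cs <= 0)) stop("zero column sum: cannot normalize kernel")
  nz <- nz_row_counts(K, eps)
  if (any(nz == 0)) stop("zero nonzero-count row: cannot normalize kernel")
  if (variant == "full_denominator") {
    K / outer(nz, cs)
  } else {
    K * outer(nz, 1 / cs)
  }
}
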