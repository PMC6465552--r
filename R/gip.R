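#' Gaussian interaction-profile kernel bandwidth
#'
#' The bandwidth is the supplied scale parameter divided by the mean squared
#' norm of the interaction profiles on the chosen axis:
#' `gamma = gamma_prime / mean(||IP(i)||^2)`. Microbe profiles are the
#' columns of the adjacency, disease profiles the rows.
#'
#' @param A binary adjacency matrix (diseases x microbes).
#' @param axis `"microbe"` (profiles are columns) or `"disease"` (rows).
#' @param gamma_prime positive bandwidth scale; 1 by default.
#' @return The positive bandwidth `gamma`.
#' @export
gip_bandwidth <- function(A, axis = c("microbe", "disease"),
                          gamma_prime = 1) {
  axis <- match.arg(axis)
  A <- as.matrix(A)
  stopifnot(gamma_prime > 0)
  sqnorm <- if (axis == "microbe") colSums(A^2) else rowSums(A^2)
  m <- mean(sqnorm)
  if (m == 0) stop("zero bandwidth denominator: all interaction profiles are empty")
  gamma_prime / m
}

#' Gaussian interaction-profile kernel matrix
#'
#' Similarity between two nodes on the same axis is
#' `K(i, j) = exp(-gamma * ||IP(i) - IP(j)||^2)` with `gamma` from
#' [gip_bandwidth()]. The result is symmetric with a unit diagonal and
#' entries in (0, 1]; `K(i, j) = 1` exactly when the two profiles coincide.
#'
#' @inheritParams gip_bandwidth
#' @return A square kernel matrix (microbes x microbes or diseases x
#'   diseases) with `gamma` attached as attribute `"gamma"`.
#' @examples
#' A <- diag(2)
#' gip_kernel(A, "microbe")  # off-diagonal exp(-2)
#' @export
gip_kernel <- function(A, axis = c("microbe", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  A <- as.matrix(A)
  gamma <- gip_bandwidth(A, axis, gamma_prime)
  P <- if (axis == "microbe") t(A) else A     # profiles as rows
  sq <- rowSums(P^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0                             # numerical guard
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  attr(K, "gamma") <- gamma
  K
}

#' Kernel pair for both axes
#'
#' Convenience wrapper computing the microbe and disease kernels of a
#' dataset together with their bandwidths.
#'
#' @param dataset an [association_dataset()] (or a bare binary matrix).
#' @param gamma_prime_m,gamma_prime_d bandwidth scales for the microbe and
#'   disease kernels.
#' @return A list of class `gip_kernels` with elements `KM`, `KD`,
#'   `gamma_m`, `gamma_d`, `gamma_prime_m`, `gamma_prime_d`.
#' @export
gip_kernel_pair <- function(dataset, gamma_prime_m = 1, gamma_prime_d = 1) {
  A <- if (inherits(dataset, "association_dataset")) dataset$adjacency
       else as.matrix(dataset)
  KM <- gip_kernel(A, "microbe", gamma_prime_m)
  KD <- gip_kernel(A, "disease", gamma_prime_d)
  structure(
    list(KM = KM, KD = KD,
         gamma_m = attr(KM, "gamma"), gamma_d = attr(KD, "gamma"),
         gamma_prime_m = gamma_prime_m, gamma_prime_d = gamma_prime_d),
    class = "gip_kernels"
  )
}
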