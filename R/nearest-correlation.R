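#' Nearest valid correlation matrix
#'
#' Projects a symmetric unit-diagonal matrix to the nearest (Frobenius
#' norm) positive-semidefinite correlation matrix using Higham's
#' alternating-projections method (via [Matrix::nearPD()]). Correlation
#' matrices printed at two decimals are frequently slightly indefinite;
#' this repairs them before they parameterize a multivariate-normal
#' simulation.
#'
#' An input that is already positive semidefinite (smallest eigenvalue
#' `>= -tol`) is returned unchanged, which makes the operation idempotent.
#'
#' @param m square symmetric numeric matrix with unit diagonal.
#' @param tol eigenvalue tolerance below which the input counts as already
#'   valid. Default `1e-8`.
#' @return A symmetric positive-semidefinite matrix with unit diagonal and
#'   the input's dimnames. Attribute `max_shift` records the largest
#'   absolute entry change introduced by the projection.
#' @examples
#' m <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
#' nearest_correlation(m)
#' @export
nearest_correlation <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop("input must be a square numeric matrix")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("input must be symmetric")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop("input must have unit diagonal")
  }
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol) {
    attr(m, "max_shift") <- 0
    return(m)
  }
  out <- as.matrix(Matrix::nearPD(m, corr = TRUE)$mat)
  dimnames(out) <- dimnames(m)
  attr(out, "max_shift") <- max(abs(out - m))
  out
}
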