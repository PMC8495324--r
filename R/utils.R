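#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Project a symmetric matrix to the nearest positive semidefinite matrix
#'
#' Eigenvalue clipping at zero, followed by rescaling to a unit diagonal so the
#' result remains a correlation matrix.
#'
#' @param m symmetric numeric matrix with unit diagonal (a target correlation
#'   matrix, possibly indefinite).
#' @param eps eigenvalues below this value are clipped to `eps`.
#' @return positive semidefinite correlation matrix of the same dimension.
#' @export
nearest_psd <- function(m, eps = 1e-8) {
  stop_if(!isSymmetric(unname(m), tol = 1e-8), "matrix must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

## standardize columns of a matrix to zero mean, unit (sample) variance
scale_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x), "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1))
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}
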