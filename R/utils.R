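# Internal numerical helpers.

#' Minimum-norm least-squares solve
#'
#' Solves min ||Y - X B|| column-wise by a rank-revealing SVD, returning the
#' minimum-norm solution. The rank tolerance follows the LAPACK convention:
#' max(dim) * machine epsilon * largest singular value.
#'
#' @param X design matrix (n x p).
#' @param Y response matrix or vector (n x q).
#' @param tol rank tolerance; computed from the SVD when `NULL`.
#' @return list with `coef` (p x q), `rank`, and `tol`.
#' @keywords internal
#' @noRd
.lsSolve <- function(X, Y, tol = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("design and response must have the same number of rows")
  }
  sv <- svd(X)
  if (is.null(tol)) {
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  }
  r <- sum(sv$d > tol)
  if (r == 0L) {
    stop("design matrix is numerically zero: no usable information to solve")
  }
  idx <- seq_len(r)
  coef <- sv$v[, idx, drop = FALSE] %*%
    (crossprod(sv$u[, idx, drop = FALSE], Y) / sv$d[idx])
  rownames(coef) <- colnames(X)
  colnames(coef) <- colnames(Y)
  list(coef = coef, rank = r, tol = tol)
}

#' Numerical rank of a matrix (SVD, LAPACK-style tolerance)
#' @keywords internal
#' @noRd
.matRank <- function(X, tol = NULL) {
  X <- as.matrix(X)
  if (length(X) == 0L) return(0L)
  d <- svd(X, nu = 0L, nv = 0L)$d
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * d[1L]
  sum(d > tol)
}

#' @keywords internal
#' @noRd
.checkFiniteMatrix <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (any(!is.finite(x))) stop(what, " contains non-finite values")
  invisible(TRUE)
}
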