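# Classical least squares core.
#
# The Beer-Lambert mixture model A = C K + E: A (L x P) observed spectra,
# C (L x M) component quantities, K (M x P) pure-component spectra. Fitting
# estimates K from known C; prediction inverts the fitted K to estimate the
# components of a new spectrum. Both directions are ordinary least-squares
# problems, solved here by a rank-revealing SVD rather than literal
# (C'C)^-1 C' normal equations, which are numerically fragile for the long,
# smooth, nearly collinear matrices typical of vibrational spectra.

#' Center spectra and components around the calibration mean
#'
#' Column-centers a spectra matrix and its paired component matrix, returning
#' the means so that the identical transform can be re-applied at prediction
#' time and inverted exactly.
#'
#' @param A L x P spectra matrix (samples in rows).
#' @param C L x M component matrix.
#' @return list with `A`, `C` (centered) and `state`, a list holding
#'   `spectraMean` (length P) and `componentMean` (length M).
#' @examples
#' cc <- meanCenter(matrix(1:6, 3), cbind(x = c(1, 2, 3)))
#' cc$C            # -1, 0, 1
#' cc$state$componentMean
#' @export
meanCenter <- function(A, C) {
  A <- as.matrix(A)
  C <- as.matrix(C)
  if (nrow(A) < 2L) stop("degenerate input: centering needs at least 2 samples")
  if (nrow(A) != nrow(C)) stop("A and C must have the same number of rows")
  sm <- colMeans(A)
  cm <- colMeans(C)
  list(
    A = sweep(A, 2L, sm, `-`),
    C = sweep(C, 2L, cm, `-`),
    state = list(spectraMean = sm, componentMean = cm)
  )
}

#' Fit pure-component spectra by classical least squares
#'
#' Least-squares estimate of the pure-component spectra K in A = C K + E,
#' the rank-revealing equivalent of K = (C'C)^-1 C' A. The component matrix
#' must have full column rank: a rank-deficient C means some components are
#' linear combinations of others and their spectra are not identifiable.
#'
#' @param C L x M component matrix (analyte concentrations, possibly with
#'   appended pseudo-component columns).
#' @param A L x P spectra matrix.
#' @return M x P matrix of fitted pure-component spectra, rows named after
#'   the columns of `C`.
#' @examples
#' C <- cbind(a = c(1, 2))
#' A <- rbind(c(2, 4), c(4, 8))
#' fitCLS(C, A)    # one row: 2 4
#' @seealso [predictCLS()], [meanCenter()]
#' @export
fitCLS <- function(C, A) {
  C <- as.matrix(C)
  A <- as.matrix(A)
  if (nrow(C) != nrow(A)) stop("C and A must have the same number of rows")
  .checkFiniteMatrix(C, "C")
  .checkFiniteMatrix(A, "A")
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- qrC$pivot[seq.int(qrC$rank + 1L, ncol(C))]
    lab <- if (is.null(colnames(C))) paste0("column ", bad) else colnames(C)[bad]
    stop("component matrix is collinear; offending column(s): ",
         paste(lab, collapse = ", "))
  }
  K <- .lsSolve(C, A)$coef
  rownames(K) <- colnames(C)
  K
}

#' Predict component quantities from spectra
#'
#' Inverts a fitted pure-spectra matrix: each centered spectrum a is mapped to
#' the component estimate minimizing ||a - c K||, the rank-revealing
#' equivalent of C = A K' (K K')^-1. When K is rank deficient (for example
#' after augmenting with columns orthogonal to every true component, whose
#' fitted spectra are numerically zero) the minimum-norm solution is returned
#' with a warning; only a numerically zero K is an error.
#'
#' @param A L x P spectra matrix of new observations.
#' @param K M x P fitted pure-spectra matrix.
#' @param state optional centering state from [meanCenter()]; when supplied,
#'   `state$spectraMean` is subtracted from `A` and `state$componentMean`
#'   added back to the predictions.
#' @param target column (index or name) of the analyte of interest.
#' @return list with `concentrations` (L x M predicted component matrix in
#'   original units; pseudo-component columns are bookkeeping, not chemistry)
#'   and `target` (numeric vector, the analyte of interest).
#' @examples
#' K <- matrix(1, 1, 4)
#' predictCLS(3 * K, K)$target   # 3
#' @export
predictCLS <- function(A, K, state = NULL, target = 1L) {
  A <- as.matrix(A)
  K <- as.matrix(K)
  if (ncol(A) != ncol(K)) stop("A and K must share the wavenumber axis")
  if (!is.null(state)) A <- sweep(A, 2L, state$spectraMean, `-`)
  sol <- .lsSolve(t(K), t(A))
  if (sol$rank < nrow(K)) {
    warning("pure-spectra estimate is rank deficient (rank ", sol$rank,
            " of ", nrow(K), "); minimum-norm component estimates returned")
  }
  Chat <- t(sol$coef)
  colnames(Chat) <- rownames(K)
  if (!is.null(state)) Chat <- sweep(Chat, 2L, state$componentMean, `+`)
  tgt <- if (is.character(target)) match(target, colnames(Chat)) else as.integer(target)
  if (is.na(tgt) || tgt < 1L || tgt > ncol(Chat)) stop("unknown target column")
  list(concentrations = Chat, target = as.numeric(Chat[, tgt]))
}
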