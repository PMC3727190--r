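# High-level calibration methods operating on a RamanExperiment. All methods
# share one contract: fit on a calibration experiment, predict the target
# analyte (in original concentration units) for new spectra via
# predictConcentration().

.targetIndex <- function(target, labels) {
  tgt <- if (is.character(target)) match(target, labels) else as.integer(target)
  if (is.na(tgt) || tgt < 1L || tgt > length(labels)) {
    stop("unknown target analyte: ", target)
  }
  tgt
}

# Shared assembly of a CLS-family model from (possibly augmented) matrices.
.makeCLSModel <- function(class, method, A, Caug, targetName, wavenumber,
                          center, rmsecv = NA_real_, extra = list()) {
  kind <- attr(Caug, "componentKind")
  if (is.null(kind)) kind <- rep("analyte", ncol(Caug))
  src <- attr(Caug, "sourceChannel")
  if (is.null(src)) src <- rep(NA_integer_, ncol(Caug))
  if (center) {
    cc <- meanCenter(A, Caug)
    K <- fitCLS(cc$C, cc$A)
    sm <- cc$state$spectraMean
    cm <- cc$state$componentMean
  } else {
    K <- fitCLS(Caug, A)
    sm <- numeric(0)
    cm <- numeric(0)
  }
  args <- c(list(class,
    method = method, target = targetName,
    spectraMean = sm, componentMean = cm, centered = center,
    wavenumber = as.numeric(wavenumber), rmsecv = rmsecv,
    pureSpectra = K, componentKind = kind, sourceChannel = as.integer(src)
  ), extra)
  do.call(methods::new, args)
}

.asIntensityMatrix <- function(newdata, wavenumber) {
  if (methods::is(newdata, "RamanExperiment")) {
    if (!isTRUE(all.equal(wavenumbers(newdata), wavenumber))) {
      stop("wavenumber axis of newdata does not match the calibration axis")
    }
    intensities(newdata)
  } else {
    m <- as.matrix(newdata)
    if (ncol(m) != length(wavenumber)) {
      stop("newdata must have one column per calibration wavenumber channel")
    }
    m
  }
}

#' Fit the classical least squares baselines
#'
#' `fitCLS1()` uses only the target analyte's concentration column (the
#' traditional, information-starved CLS); `fitCLS2()` uses all known analyte
#' concentrations. Both center spectra and concentrations around the
#' calibration mean by default.
#'
#' @param re calibration [RamanExperiment].
#' @param target target analyte (name or index into [analyteNames()]);
#'   defaults to the first analyte.
#' @param center center around the calibration mean (default TRUE).
#' @return a [CLSCalibration][CalibrationModel] model.
#' @seealso [fitACLS()], [fitCRACLS()], [predictConcentration()]
#' @export
fitCLS1 <- function(re, target = 1L, center = TRUE) {
  C <- concentrations(re)
  tgt <- .targetIndex(target, colnames(C))
  .makeCLSModel("CLSCalibration", "cls1", intensities(re),
                C[, tgt, drop = FALSE], colnames(C)[tgt],
                wavenumbers(re), center)
}

#' @rdname fitCLS1
#' @export
fitCLS2 <- function(re, target = 1L, center = TRUE) {
  C <- concentrations(re)
  tgt <- .targetIndex(target, colnames(C))
  .makeCLSModel("CLSCalibration", "cls2", intensities(re), C,
                colnames(C)[tgt], wavenumbers(re), center)
}

#' Fit concentration-residual augmented CLS (CRACLS)
#'
#' Starts from the all-analyte CLS fit and iterates: predict the calibration
#' target concentrations, append the residual vector (predicted minus
#' reference) to the component matrix as a pseudo-component, refit. The
#' residuals carry the part of the unmodeled spectral variance that projects
#' onto the target, so successive fits absorb it. Iteration stops when the
#' residual norm improves by less than `tol` (relative), the residual is
#' numerically zero, the augmented matrix would lose rank, or `maxIter` is
#' reached; a step that worsens the calibration residual is rolled back.
#'
#' @inheritParams fitCLS1
#' @param maxIter maximum number of appended residual columns (default 10).
#' @param tol relative improvement in residual norm below which iteration
#'   stops (default 1e-8).
#' @return a [CLSCalibration][CalibrationModel] model with
#'   `componentKind == "residual"` for the appended columns.
#' @export
fitCRACLS <- function(re, target = 1L, maxIter = 10L, tol = 1e-8,
                      center = TRUE) {
  A <- intensities(re)
  C0 <- concentrations(re)
  tgt <- .targetIndex(target, colnames(C0))
  ref <- C0[, tgt]
  Ccur <- C0
  kind <- rep("analyte", ncol(C0))
  prevNorm <- Inf
  best <- NULL
  bestRmse <- Inf
  for (it in seq_len(maxIter + 1L)) {
    model <- .makeCLSModel("CLSCalibration", "cracls", A, Ccur,
                           colnames(C0)[tgt], wavenumbers(re), center)
    model@componentKind <- kind
    pred <- predictConcentration(model, A)
    resid <- pred - ref
    rmseCal <- sqrt(mean(resid^2))
    if (rmseCal < bestRmse) {
      best <- model
      bestRmse <- rmseCal
    } else {
      break   # calibration residual worsened: keep the previous fit
    }
    rnorm <- sqrt(sum(resid^2))
    if (it > maxIter) break
    if (rnorm <= tol * max(1, sqrt(sum(ref^2)))) break               # converged
    if (prevNorm - rnorm < tol * max(prevNorm, .Machine$double.eps) &&
        is.finite(prevNorm)) break                                    # stalled
    cand <- cbind(Ccur, resid)
    if (.matRank(cand) <= .matRank(Ccur)) break        # rank guard: ~0 column
    if (ncol(cand) + 1L >= nrow(A)) break              # overfit guard
    colnames(cand)[ncol(cand)] <- paste0("resid", it)
    Ccur <- cand
    kind <- c(kind, "residual")
    prevNorm <- rnorm
  }
  best
}

#' Fit augmented classical least squares (ACLS)
#'
#' The full channel-augmentation pipeline: per-channel squared correlations
#' with the target ([channelR2()]), low-correlation region-separated
#' candidate ranking ([rankCandidates()]), a leave-one-out RMSECV curve over
#' augmentation sizes ([looRmsecvCurve()]), elbow selection
#' ([chooseAugmentationSize()]), and a final CLS fit on the augmented
#' component matrix.
#'
#' By default the component matrix holds all known analyte concentrations
#' (`baseComponents = "all"`, the same matrix the all-analyte CLS baseline
#' uses) and the appended channels stand in for the unknown remainder —
#' unconsidered species, nonlinearity, instrument effects. With
#' `baseComponents = "target"` the channels must proxy the other known
#' species too, the setting of interest when only the target analyte's
#' reference values exist.
#'
#' @inheritParams fitCLS1
#' @param baseComponents `"all"` (default) or `"target"`: which analyte
#'   columns to keep in the component matrix before augmentation.
#' @param r2Threshold candidate channels must have squared target correlation
#'   below this value (default 0.2).
#' @param minSpacing minimum wavenumber gap between selected channels in
#'   1/cm (default 100).
#' @param mMax largest augmentation size scanned by the RMSECV curve;
#'   defaults to the most the candidate list and sample count allow, capped
#'   at 30.
#' @param m explicit augmentation size, bypassing elbow detection (for
#'   example to replicate a visually read elbow); NULL (default) selects
#'   automatically.
#' @return an [ACLSCalibration][CalibrationModel] model.
#' @export
fitACLS <- function(re, target = 1L, baseComponents = c("all", "target"),
                    r2Threshold = 0.2, minSpacing = 100, mMax = NULL,
                    m = NULL, center = TRUE) {
  baseComponents <- match.arg(baseComponents)
  A <- intensities(re)
  Call <- concentrations(re)
  tgt <- .targetIndex(target, colnames(Call))
  Cbase <- if (baseComponents == "target") Call[, tgt, drop = FALSE] else Call
  baseTgt <- if (baseComponents == "target") 1L else tgt
  wn <- wavenumbers(re)

  r2 <- channelR2(A, Call[, tgt])
  cand <- rankCandidates(r2, wn, r2Threshold, minSpacing)
  if (is.null(mMax)) {
    mMax <- min(30L, length(cand), nrow(A) - ncol(Cbase) - 3L)
  }
  if (mMax < 0L) stop("not enough samples for any augmentation")
  curve <- looRmsecvCurve(A, Cbase, cand, mMax, target = baseTgt,
                          center = center)
  chosen <- chooseAugmentationSize(curve, override = m)
  if (chosen > length(cand)) {
    stop("requested augmentation size exceeds the candidate list (",
         length(cand), " channels)")
  }
  chosenCh <- cand[seq_len(chosen)]
  Caug <- augmentConcentrationMatrix(Cbase, A, chosenCh)
  rmsecvAt <- if (chosen + 1L <= length(curve)) curve[[chosen + 1L]] else NA_real_
  .makeCLSModel("ACLSCalibration", "acls", A, Caug, colnames(Call)[tgt],
                wn, center, rmsecv = rmsecvAt,
                extra = list(r2 = r2, candidateOrder = as.integer(cand),
                             rmsecvCurve = as.numeric(curve),
                             chosenM = as.integer(chosen)))
}

# ---- inverse (latent-variable) models -------------------------------------

# Cumulative PCR coefficient vectors: column k is the regression vector of
# the centered target on the leading k principal-component scores.
.pcrCoefAll <- function(Ac, yc, kMax) {
  sv <- svd(Ac)
  r <- sum(sv$d > max(dim(Ac)) * .Machine$double.eps * sv$d[1L])
  kMax <- min(kMax, r)
  g <- as.numeric(crossprod(sv$u[, seq_len(kMax), drop = FALSE], yc)) /
    sv$d[seq_len(kMax)]
  steps <- sweep(sv$v[, seq_len(kMax), drop = FALSE], 2L, g, `*`)
  B <- apply(steps, 1L, cumsum)
  B <- if (kMax == 1L) matrix(steps, ncol = 1L) else t(B)
  list(B = B, loadings = sv$v[, seq_len(kMax), drop = FALSE], kMax = kMax,
       d = sv$d)
}

# Univariate-target NIPALS PLS with deflation; returns per-k coefficient
# vectors so one decomposition serves all component counts.
.plsCoefAll <- function(Ac, yc, kMax) {
  P <- ncol(Ac)
  W <- matrix(0, P, 0)
  Pl <- matrix(0, P, 0)
  q <- numeric(0)
  Xc <- Ac
  yr <- yc
  scale0 <- sqrt(sum(Ac^2)) * sqrt(sum(yc^2))
  k <- 0L
  scores <- matrix(0, nrow(Ac), 0)
  while (k < kMax) {
    w <- as.numeric(crossprod(Xc, yr))
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.eps * max(scale0, 1)) {
      warning("PLS stopped early at ", k,
              " components: remaining covariance is numerically zero")
      break
    }
    w <- w / nw
    tt <- as.numeric(Xc %*% w)
    t2 <- sum(tt^2)
    if (t2 <= (.Machine$double.eps * max(scale0, 1))^2) {
      warning("PLS stopped early at ", k, " components: degenerate score")
      break
    }
    p <- as.numeric(crossprod(Xc, tt)) / t2
    qk <- sum(yr * tt) / t2
    Xc <- Xc - tcrossprod(tt, p)
    yr <- yr - qk * tt
    W <- cbind(W, w)
    Pl <- cbind(Pl, p)
    q <- c(q, qk)
    scores <- cbind(scores, tt)
    k <- k + 1L
  }
  if (k == 0L) stop("PLS found no usable covariance direction")
  B <- matrix(0, P, k)
  for (j in seq_len(k)) {
    R <- solve(crossprod(Pl[, seq_len(j), drop = FALSE],
                         W[, seq_len(j), drop = FALSE]),
               q[seq_len(j)])
    B[, j] <- W[, seq_len(j), drop = FALSE] %*% R
  }
  list(B = B, loadings = Pl, weights = W, scores = scores, kMax = k)
}

.makeLatentModel <- function(method, A, y, targetName, wavenumber, k,
                             rmsecv = NA_real_) {
  sm <- colMeans(A)
  ym <- mean(y)
  Ac <- sweep(A, 2L, sm, `-`)
  yc <- y - ym
  dec <- if (method == "pcr") .pcrCoefAll(Ac, yc, k) else .plsCoefAll(Ac, yc, k)
  k <- min(k, dec$kMax)
  coef <- dec$B[, k]
  methods::new("LatentCalibration",
    method = method, target = targetName, spectraMean = sm,
    componentMean = stats::setNames(ym, targetName), centered = TRUE,
    wavenumber = as.numeric(wavenumber), rmsecv = rmsecv,
    coefficients = as.numeric(coef),
    intercept = ym - sum(sm * coef),
    nComponents = as.integer(k),
    loadings = dec$loadings[, seq_len(k), drop = FALSE])
}

#' Fit principal component regression (PCR) or partial least squares (PLS)
#'
#' Inverse calibration of the target analyte on the spectra: PCR regresses
#' the centered target on the leading principal-component scores of the
#' centered spectra; PLS extracts covariance-maximizing latent variables by
#' the classical univariate NIPALS algorithm with deflation. Prediction is an
#' affine map of a new spectrum. When `nComponents` is NULL the count is
#' chosen by [selectNumComponents()]: the smallest count whose leave-one-out
#' RMSECV is within a relative tolerance of the curve minimum.
#'
#' @inheritParams fitCLS1
#' @param nComponents number of components / latent variables; NULL (default)
#'   selects by leave-one-out RMSECV.
#' @param kMax largest count scanned during selection (default
#'   `min(15, L - 2)`).
#' @param selectTol relative RMSECV tolerance of the selection rule
#'   (default 0.02).
#' @return a [LatentCalibration][CalibrationModel] model.
#' @export
fitPCR <- function(re, target = 1L, nComponents = NULL, kMax = NULL,
                   selectTol = 0.02) {
  .fitLatent(re, target, "pcr", nComponents, kMax, selectTol)
}

#' @rdname fitPCR
#' @export
fitPLS <- function(re, target = 1L, nComponents = NULL, kMax = NULL,
                   selectTol = 0.02) {
  .fitLatent(re, target, "pls", nComponents, kMax, selectTol)
}

.fitLatent <- function(re, target, method, nComponents, kMax, selectTol) {
  A <- intensities(re)
  C <- concentrations(re)
  tgt <- .targetIndex(target, colnames(C))
  y <- C[, tgt]
  rmsecvAt <- NA_real_
  if (is.null(nComponents)) {
    if (is.null(kMax)) kMax <- min(15L, nrow(A) - 2L)
    k <- selectNumComponents(A, y, method = method, kMax = kMax,
                             tol = selectTol)
    rmsecvAt <- attr(k, "rmsecv")[k]
    nComponents <- as.integer(k)
  }
  if (nComponents < 1L || nComponents > min(nrow(A) - 1L, ncol(A))) {
    stop("nComponents must lie in 1..min(L-1, P)")
  }
  .makeLatentModel(method, A, y, colnames(C)[tgt], wavenumbers(re),
                   nComponents, rmsecv = rmsecvAt)
}

#' Pick a component count from an RMSECV curve
#'
#' The smallest count whose RMSECV is within `tol` (relative) of the curve
#' minimum — the parsimony rule commonly used to avoid over-fitting latent
#' variable counts.
#'
#' @param rmsecv RMSECV values for k = 1..kMax.
#' @param tol relative tolerance (default 0.02).
#' @return integer count.
#' @examples
#' pickComponentCount(c(5, 1, 0.99, 0.995))   # 2
#' @export
pickComponentCount <- function(rmsecv, tol = 0.02) {
  if (all(is.na(rmsecv))) stop("RMSECV curve contains no finite values")
  lim <- (1 + tol) * min(rmsecv, na.rm = TRUE)
  as.integer(which(rmsecv <= lim)[1L])
}

#' Select the number of latent components by leave-one-out RMSECV
#'
#' Computes the exhaustive leave-one-out RMSECV of PCR or PLS for k =
#' 1..kMax and applies [pickComponentCount()].
#'
#' @param A L x P calibration spectra matrix.
#' @param y length-L target concentration vector.
#' @param method `"pcr"` or `"pls"`.
#' @param kMax largest component count scanned.
#' @param tol relative tolerance of the pick rule (default 0.02).
#' @return integer count with attribute `"rmsecv"`, the curve.
#' @export
selectNumComponents <- function(A, y, method = c("pcr", "pls"), kMax,
                                tol = 0.02) {
  method <- match.arg(method)
  A <- as.matrix(A)
  y <- as.numeric(y)
  L <- nrow(A)
  if (kMax < 1L) stop("kMax must be at least 1")
  kMax <- min(kMax, L - 2L, ncol(A))
  press <- matrix(NA_real_, L, kMax)
  for (i in seq_len(L)) {
    Atr <- A[-i, , drop = FALSE]
    ytr <- y[-i]
    sm <- colMeans(Atr)
    ym <- mean(ytr)
    Ac <- sweep(Atr, 2L, sm, `-`)
    dec <- if (method == "pcr") .pcrCoefAll(Ac, ytr - ym, kMax)
           else suppressWarnings(.plsCoefAll(Ac, ytr - ym, kMax))
    xc <- A[i, ] - sm
    kk <- dec$kMax
    press[i, seq_len(kk)] <- (as.numeric(xc %*% dec$B[, seq_len(kk),
                                                      drop = FALSE]) +
                                ym - y[i])^2
  }
  rmsecv <- sqrt(colMeans(press))
  k <- pickComponentCount(rmsecv, tol)
  attr(k, "rmsecv") <- rmsecv
  k
}

#' Fit a calibration model by method name
#'
#' Dispatcher over the method roster: `"cls1"`, `"cls2"`, `"cracls"`,
#' `"pcr"`, `"pls"`, `"acls"`.
#'
#' @inheritParams fitCLS1
#' @param method method tag.
#' @param ... passed to the specific fitter.
#' @return a [CalibrationModel].
#' @export
calibrate <- function(re, method = c("cls1", "cls2", "cracls", "pcr", "pls",
                                     "acls"),
                      target = 1L, ...) {
  method <- match.arg(method)
  switch(method,
    cls1 = fitCLS1(re, target, ...),
    cls2 = fitCLS2(re, target, ...),
    cracls = fitCRACLS(re, target, ...),
    pcr = fitPCR(re, target, ...),
    pls = fitPLS(re, target, ...),
    acls = fitACLS(re, target, ...)
  )
}

# ---- prediction and accessors ---------------------------------------------

#' @rdname predictConcentration
#' @param full return the complete predicted component matrix instead of the
#'   target vector (CLS-family models).
#' @export
setMethod("predictConcentration", "CLSCalibration",
  function(object, newdata, full = FALSE) {
    A <- .asIntensityMatrix(newdata, object@wavenumber)
    state <- if (object@centered) {
      list(spectraMean = object@spectraMean, componentMean = object@componentMean)
    } else NULL
    tgt <- object@target
    if (!tgt %in% rownames(object@pureSpectra)) tgt <- 1L
    pred <- predictCLS(A, object@pureSpectra, state, target = tgt)
    if (full) pred$concentrations else pred$target
  })

#' @rdname predictConcentration
#' @export
setMethod("predictConcentration", "LatentCalibration",
  function(object, newdata) {
    A <- .asIntensityMatrix(newdata, object@wavenumber)
    as.numeric(A %*% object@coefficients + object@intercept)
  })

#' @rdname pureSpectra
#' @export
setMethod("pureSpectra", "CLSCalibration", function(x) x@pureSpectra)

#' @rdname augmentedChannels
#' @export
setMethod("augmentedChannels", "ACLSCalibration",
          function(x) x@sourceChannel[x@componentKind == "channel"])

#' @rdname rmsecvCurve
#' @export
setMethod("rmsecvCurve", "ACLSCalibration", function(x) x@rmsecvCurve)

setMethod("show", "CLSCalibration", function(object) {
  cat(toupper(object@method), " calibration for target '", object@target,
      "'\n", sep = "")
  tab <- table(object@componentKind)
  cat("  components:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  if (!is.na(object@rmsecv)) cat("  calibration RMSECV:",
                                 format(object@rmsecv, digits = 5), "\n")
  invisible(NULL)
})

setMethod("show", "ACLSCalibration", function(object) {
  methods::callNextMethod()
  cat("  augmentation: m =", object@chosenM, "channels of",
      length(object@candidateOrder), "candidates\n")
  invisible(NULL)
})

setMethod("show", "LatentCalibration", function(object) {
  cat(toupper(object@method), "calibration for target '", object@target,
      "' with ", object@nComponents, " component(s)\n", sep = "")
  if (!is.na(object@rmsecv)) cat("  calibration RMSECV:",
                                 format(object@rmsecv, digits = 5), "\n")
  invisible(NULL)
})
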