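# Concentration-matrix augmentation with low-correlation spectral channels.
#
# CLS needs every component contributing spectral variance in its C matrix;
# species, drifts and instrument effects left out of C corrupt the fitted
# pure spectra. The augmentation strategy implemented here appends the
# intensity columns of spectral channels that correlate poorly with the
# target analyte (squared Pearson R2 below a cut, default 0.2) as
# pseudo-components: such channels are driven mostly by the unmodeled
# variance and stand in for the missing component quantities. The number of
# appended channels is sized from the elbow of a leave-one-out RMSECV curve.

#' Squared correlation of every spectral channel with the target analyte
#'
#' @param A L x P spectra matrix over the calibration samples.
#' @param target length-L concentration vector of the analyte of interest.
#' @return numeric vector of length P with entries in `[0, 1]`; constant
#'   channels are assigned 0 by convention.
#' @examples
#' A <- cbind(c(1, 2, 3), c(5, 5, 5))
#' channelR2(A, c(1, 2, 3))   # 1, 0
#' @export
channelR2 <- function(A, target) {
  A <- as.matrix(A)
  target <- as.numeric(target)
  if (nrow(A) < 3L) stop("channel correlations need at least 3 samples")
  if (length(target) != nrow(A)) stop("target length must match rows of A")
  tc <- target - mean(target)
  sst <- sum(tc^2)
  if (sst <= 0) stop("degenerate target: concentration vector is constant")
  Ac <- sweep(A, 2L, colMeans(A), `-`)
  ssa <- colSums(Ac^2)
  num <- as.numeric(crossprod(Ac, tc))^2
  r2 <- numeric(ncol(A))
  ok <- ssa > max(ssa, sst) * .Machine$double.eps^2 * nrow(A)
  r2[ok] <- num[ok] / (ssa[ok] * sst)
  pmin(pmax(r2, 0), 1)
}

#' Rank augmentation candidates by ascending correlation, region-separated
#'
#' Channels with squared correlation below `r2Threshold` are sorted by
#' ascending r2 and greedily filtered so that every retained channel lies at
#' least `minSpacing` 1/cm away from all previously retained ones. The
#' spacing rule spreads the picks over different wavenumber regions:
#' neighbouring channels of a smooth spectrum are mutually correlated and
#' would be redundant pseudo-components.
#'
#' @param r2 per-channel squared correlations from [channelR2()].
#' @param wavenumber the wavenumber axis (1/cm), same length as `r2`.
#' @param r2Threshold keep only channels with `r2 < r2Threshold` (default 0.2).
#' @param minSpacing minimum wavenumber gap between retained channels, in
#'   1/cm (default 100).
#' @return integer vector of channel indices in selection order.
#' @export
rankCandidates <- function(r2, wavenumber, r2Threshold = 0.2, minSpacing = 100) {
  if (length(r2) != length(wavenumber)) stop("r2 and wavenumber lengths differ")
  below <- which(r2 < r2Threshold)
  if (length(below) == 0L) {
    stop("no channel has r2 below the threshold ", r2Threshold)
  }
  ord <- below[order(r2[below], below)]
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) == 0L ||
        all(abs(wavenumber[kept] - wavenumber[j]) >= minSpacing)) {
      kept <- c(kept, j)
    }
  }
  kept
}

#' Append spectral channels to a component matrix as pseudo-components
#'
#' @param C L x M component matrix; analyte columns are left untouched.
#' @param A L x P spectra matrix aligned with `C`.
#' @param channels integer channel indices to append, in order.
#' @param warn emit a warning when a collinear channel is dropped.
#' @return the augmented component matrix with attributes `componentKind`
#'   (per column, "analyte"/"channel") and `sourceChannel` (the channel index
#'   behind each pseudo-column, NA for analytes). Channels whose intensity
#'   column is numerically a linear combination of columns already present
#'   are dropped (smooth spectra make near-duplicate channels common).
#' @export
augmentConcentrationMatrix <- function(C, A, channels, warn = TRUE) {
  C <- as.matrix(C)
  A <- as.matrix(A)
  channels <- as.integer(channels)
  if (length(channels) && (min(channels) < 1L || max(channels) > ncol(A))) {
    stop("channel indices out of range")
  }
  kind <- attr(C, "componentKind")
  if (is.null(kind)) kind <- rep("analyte", ncol(C))
  src <- attr(C, "sourceChannel")
  if (is.null(src)) src <- rep(NA_integer_, ncol(C))
  out <- C
  dropped <- integer(0)
  for (j in channels) {
    if (ncol(out) + 1L >= nrow(out)) {
      stop("overfit guard: augmented component count must stay below the ",
           "number of calibration samples")
    }
    v <- A[, j]
    cand <- cbind(out, v)
    if (.matRank(cand) <= .matRank(out)) {
      dropped <- c(dropped, j)
      next
    }
    out <- cand
    colnames(out)[ncol(out)] <- paste0("ch", j)
    kind <- c(kind, "channel")
    src <- c(src, j)
  }
  if (length(dropped) && warn) {
    warning("dropped collinear channel(s): ", paste(dropped, collapse = ", "))
  }
  attr(out, "componentKind") <- kind
  attr(out, "sourceChannel") <- src
  out
}

# Leave-one-out CLS predictions of the target analyte for a fixed component
# matrix; returns the prediction vector, refitting (and re-centering) for
# every left-out sample.
.looPredictCLS <- function(A, C, target = 1L, center = TRUE) {
  L <- nrow(A)
  pred <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    Atr <- A[-i, , drop = FALSE]
    Ctr <- C[-i, , drop = FALSE]
    if (center) {
      cc <- meanCenter(Atr, Ctr)
      K <- fitCLS(cc$C, cc$A)
      pred[i] <- predictCLS(A[i, , drop = FALSE], K, cc$state, target)$target
    } else {
      K <- fitCLS(Ctr, Atr)
      pred[i] <- predictCLS(A[i, , drop = FALSE], K, target = target)$target
    }
  }
  pred
}

#' Leave-one-out RMSECV versus augmentation size
#'
#' For m = 0..mMax, augments `C` with the first m candidate channels (the
#' channel columns are fixed; only the CLS fit is redone per left-out sample)
#' and computes the exhaustive leave-one-out RMSECV of the target analyte.
#'
#' @param A,C calibration spectra and component matrices.
#' @param candidateOrder channel indices from [rankCandidates()].
#' @param mMax largest augmentation size to evaluate.
#' @param target target column of `C` (index or name).
#' @param center center around the calibration mean within each fold
#'   (default TRUE).
#' @return numeric vector of length mMax + 1; entry m + 1 is the RMSECV with
#'   m appended channels. A size whose folds cannot be fitted (rank
#'   deficiency) is recorded as NA with a warning.
#' @export
looRmsecvCurve <- function(A, C, candidateOrder, mMax, target = 1L,
                           center = TRUE) {
  A <- as.matrix(A)
  C <- as.matrix(C)
  candidateOrder <- as.integer(candidateOrder)
  if (mMax > length(candidateOrder)) {
    stop("mMax exceeds the number of candidate channels")
  }
  tgt <- if (is.character(target)) match(target, colnames(C)) else as.integer(target)
  if (is.na(tgt)) stop("unknown target column")
  L <- nrow(A)
  if (L < ncol(C) + mMax + 2L) {
    stop("not enough samples: need L >= M + 2 at every augmentation size")
  }
  ref <- C[, tgt]
  curve <- rep(NA_real_, mMax + 1L)
  for (m in 0:mMax) {
    Caug <- suppressWarnings(
      augmentConcentrationMatrix(C, A, candidateOrder[seq_len(m)], warn = FALSE)
    )
    pred <- tryCatch(
      .looPredictCLS(A, Caug, tgt, center),
      error = function(e) {
        warning("RMSECV at m = ", m, " could not be computed: ",
                conditionMessage(e))
        NULL
      }
    )
    if (!is.null(pred)) curve[m + 1L] <- sqrt(mean((pred - ref)^2))
  }
  names(curve) <- paste0("m", 0:mMax)
  curve
}

#' Choose the augmentation size from the elbow of an RMSECV curve
#'
#' Kneedle-style elbow: the size maximizing the vertical drop below the chord
#' joining the first and last curve points (equivalently, perpendicular
#' distance up to a constant factor). Ties break toward the smaller size. If
#' the curve at the elbow is worse than at m = 0 — the unstable low-m region
#' where appended channels inject non-orthogonal noise — the choice falls
#' back to 0 with a warning. An explicit `override` (for example a visually
#' read elbow) is honored unchanged.
#'
#' @param curve RMSECV values for m = 0..mMax (NA entries are skipped).
#' @param override integer; when non-NULL, returned as-is.
#' @return the chosen augmentation size m.
#' @examples
#' chooseAugmentationSize(c(1, 0.9, 0.1, 0.09, 0.08))  # 2
#' @export
chooseAugmentationSize <- function(curve, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  curve <- as.numeric(curve)
  if (length(curve) < 3L) stop("RMSECV curve needs at least 3 points")
  ok <- which(!is.na(curve))
  if (length(ok) == 0L) stop("RMSECV curve contains no finite values")
  first <- ok[1L]
  last <- ok[length(ok)]
  m0 <- first - 1L
  m1 <- last - 1L
  if (m1 == m0) return(m0)
  slope <- (curve[last] - curve[first]) / (m1 - m0)
  drop <- rep(-Inf, length(curve))
  ms <- seq_along(curve) - 1L
  drop[ok] <- (curve[first] + slope * (ms[ok] - m0)) - curve[ok]
  chosen <- ms[which.max(drop)]   # first max: ties go to the smaller m
  if (max(drop) <= 0) chosen <- m0
  if (!is.na(curve[chosen + 1L]) && !is.na(curve[first]) &&
      curve[chosen + 1L] > curve[first]) {
    warning("RMSECV at the elbow exceeds the unaugmented RMSECV; ",
            "falling back to m = ", m0)
    chosen <- m0
  }
  as.integer(chosen)
}
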