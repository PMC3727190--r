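# Evaluation protocol: Venetian-blinds fold assignment, RMSE / R2 metrics,
# one-way ANOVA on absolute prediction errors, and the multi-method
# comparison table.

#' Venetian-blinds fold assignment
#'
#' Interleaves samples in acquisition order: the sample at position i gets
#' fold `(i - 1) mod nFolds` (0-based fold ids). For smoothly varying batch
#' processes this keeps concentration ranges and correlations similar across
#' folds. Deterministic, depends only on the order.
#'
#' @param n number of samples, or anything with a length (e.g. sample ids).
#' @param nFolds number of folds (default 2).
#' @return integer vector of fold ids in 0..nFolds-1.
#' @examples
#' venetianBlinds(5)        # 0 1 0 1 0
#' table(venetianBlinds(110))
#' @export
venetianBlinds <- function(n, nFolds = 2L) {
  L <- if (length(n) == 1L && is.numeric(n)) as.integer(n) else length(n)
  if (L < nFolds) stop("need at least one sample per fold")
  (seq_len(L) - 1L) %% as.integer(nFolds)
}

#' Root-mean-square error
#'
#' @param predicted,reference numeric vectors of equal length.
#' @return sqrt of the mean squared error, in concentration units.
#' @examples
#' rmse(c(4, 5), c(1, 1))   # sqrt(12.5)
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (length(predicted) == 0L) stop("empty input")
  sqrt(mean((as.numeric(predicted) - as.numeric(reference))^2))
}

#' Squared Pearson correlation between predictions and reference values
#'
#' @param predicted,reference numeric vectors (length >= 3); the reference
#'   must not be constant.
#' @return squared correlation coefficient.
#' @export
rSquared <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (length(reference) < 3L) stop("need at least 3 observations")
  if (stats::sd(reference) == 0) stop("constant reference values")
  as.numeric(stats::cor(predicted, reference))^2
}

#' One-way ANOVA on absolute prediction errors
#'
#' Fixed-effects one-way ANOVA across groups of absolute prediction errors,
#' the significance test used to compare calibration models. For two groups
#' the F statistic equals the square of the pooled two-sample t statistic and
#' the p values coincide. Identical groups (no between- or within-group
#' variance) return F = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each of length >= 2)
#'   of absolute prediction errors, one vector per model.
#' @return list with `F`, `df` (between, within) and `p`.
#' @examples
#' anovaAbsErrors(list(c(1, 2, 3), c(2, 3, 4)))   # F = 1.5, p ~ 0.288
#' @export
anovaAbsErrors <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  dfb <- length(groups) - 1L
  dfw <- length(vals) - length(groups)
  if (stats::var(vals) == 0) {
    return(list(F = 0, df = c(between = dfb, within = dfw), p = 1))
  }
  ow <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  Fv <- as.numeric(ow$statistic)
  if (!is.finite(Fv)) {   # zero within-group variance with identical means
    Fv <- 0
    pv <- 1
  } else {
    pv <- as.numeric(ow$p.value)
  }
  list(F = Fv, df = c(between = dfb, within = dfw), p = pv)
}

# Leave-one-out RMSECV of a method on a calibration experiment, by refitting
# per left-out sample. Used for the CLS-family rows of the comparison table;
# latent and ACLS models carry the RMSECV from their own selection step.
.looRmsecvModel <- function(cal, method, target, ...) {
  L <- ncol(cal)
  ref <- concentrations(cal)[, .targetIndex(target, analyteNames(cal))]
  pred <- vapply(seq_len(L), function(i) {
    fit <- calibrate(cal[, -i], method, target, ...)
    predictConcentration(fit, cal[, i, drop = FALSE])
  }, numeric(1))
  rmse(pred, ref)
}

#' Compare calibration methods on a held-out split
#'
#' Fits each method on the calibration fold, predicts the validation fold,
#' and reports validation R2 and RMSEP, calibration RMSECV, and — after
#' sorting methods by decreasing RMSEP (increasing prediction power) — the
#' one-way ANOVA p value of each method's absolute validation errors against
#' its predecessor in the sorted order.
#'
#' @param re a [RamanExperiment].
#' @param target target analyte (name or index).
#' @param methods character vector of method tags (>= 2); see [calibrate()].
#' @param split fold assignment from [venetianBlinds()]; defaults to a
#'   2-fold Venetian-blinds split in acquisition order.
#' @param calibrationFold fold id used for calibration (default 0); all other
#'   folds form the validation set.
#' @param acls,cracls,pcr,pls optional lists of extra arguments for the
#'   respective fitters.
#' @return data.frame with columns `method`, `R2`, `RMSEP`, `p_vs_previous`
#'   and `RMSECV`, sorted by decreasing RMSEP (first p entry is NA).
#' @export
compareModels <- function(re, target = 1L, methods, split = NULL,
                          calibrationFold = 0L, acls = list(),
                          cracls = list(), pcr = list(), pls = list()) {
  if (length(methods) < 2L) stop("need at least 2 methods to compare")
  if (is.null(split)) split <- venetianBlinds(ncol(re))
  if (length(split) != ncol(re)) stop("split length must match sample count")
  cal <- re[, split == calibrationFold]
  val <- re[, split != calibrationFold]
  refVal <- concentrations(val)[, .targetIndex(target, analyteNames(val))]
  extras <- list(acls = acls, cracls = cracls, pcr = pcr, pls = pls)

  rows <- lapply(methods, function(mth) {
    args <- extras[[mth]]
    if (is.null(args)) args <- list()
    fit <- do.call(calibrate, c(list(cal, mth, target), args))
    pred <- predictConcentration(fit, val)
    cv <- fit@rmsecv
    if (is.na(cv)) {
      cv <- do.call(.looRmsecvModel, c(list(cal, mth, target), args))
    }
    list(method = mth, R2 = rSquared(pred, refVal),
         RMSEP = rmse(pred, refVal), RMSECV = cv,
         abserr = abs(pred - refVal))
  })
  ord <- order(vapply(rows, `[[`, numeric(1), "RMSEP"), decreasing = TRUE)
  rows <- rows[ord]
  p <- rep(NA_real_, length(rows))
  for (i in seq_along(rows)[-1L]) {
    p[i] <- anovaAbsErrors(list(rows[[i - 1L]]$abserr, rows[[i]]$abserr))$p
  }
  data.frame(
    method = vapply(rows, `[[`, character(1), "method"),
    R2 = vapply(rows, `[[`, numeric(1), "R2"),
    RMSEP = vapply(rows, `[[`, numeric(1), "RMSEP"),
    p_vs_previous = p,
    RMSECV = vapply(rows, `[[`, numeric(1), "RMSECV"),
    stringsAsFactors = FALSE
  )
}
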