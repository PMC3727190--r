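#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' RamanExperiment: spectra with paired analyte concentrations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"intensity"` assay with spectral channels in rows (P wavenumbers) and
#' samples in columns (L observations). `rowData()$wavenumber` carries the
#' strictly increasing wavenumber axis in 1/cm; `colData()` carries the known
#' analyte concentrations (one column per analyte, names listed in
#' `metadata()$analytes`) and optionally a `batch` column identifying the
#' process run each sample came from.
#'
#' Most users construct one with [RamanExperiment()], [readDataset()], or
#' [generateDataset()].
#'
#' @aliases RamanExperiment-class
#' @export
setClass("RamanExperiment", contains = "SummarizedExperiment")

setValidity("RamanExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'intensity' is required")
  } else {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (!is.numeric(a)) msg <- c(msg, "intensities must be numeric")
    else if (any(!is.finite(a))) msg <- c(msg, "intensities must be finite")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'wavenumber' is required")
  } else {
    w <- rd$wavenumber
    if (length(w) >= 2L && any(diff(w) <= 0)) {
      msg <- c(msg, "wavenumber axis must be strictly increasing")
    }
  }
  an <- S4Vectors::metadata(object)$analytes
  if (!is.null(an) && !all(an %in% colnames(SummarizedExperiment::colData(object)))) {
    msg <- c(msg, "metadata()$analytes must name colData columns")
  }
  if (length(msg)) msg else TRUE
})

#' Calibration models
#'
#' `CalibrationModel` is the virtual parent of all calibration methods. Every
#' model stores the method tag, the target analyte name, and the calibration
#' means used for centering (spectra and components are centered around the
#' mean of the calibration set; predictions are mapped back to original
#' units).
#'
#' `CLSCalibration` covers the classical-least-squares family (CLS1, CLS2,
#' CRACLS, ACLS): it stores the fitted pure-component spectra (one row per
#' component, including appended pseudo-components) and per-column component
#' bookkeeping. `ACLSCalibration` additionally records the channel-selection
#' state: per-channel squared correlations, the candidate order, the RMSECV
#' curve, and the chosen augmentation size. `LatentCalibration` covers the
#' inverse models (PCR, PLS): prediction is an affine map of the spectrum.
#'
#' @slot method character tag ("cls1", "cls2", "cracls", "pcr", "pls", "acls").
#' @slot target name of the target analyte.
#' @slot spectraMean,componentMean calibration-set column means.
#' @slot centered whether centering was applied at fit time.
#' @slot wavenumber the calibration wavenumber axis.
#' @slot rmsecv leave-one-out RMSECV on the calibration set, when computed
#'   at fit time (NA otherwise).
#' @aliases CalibrationModel-class CLSCalibration-class ACLSCalibration-class
#'   LatentCalibration-class
#' @name CalibrationModel
NULL

#' @rdname CalibrationModel
#' @export
setClass("CalibrationModel", representation("VIRTUAL",
  method = "character",
  target = "character",
  spectraMean = "numeric",
  componentMean = "numeric",
  centered = "logical",
  wavenumber = "numeric",
  rmsecv = "numeric"
))

#' @rdname CalibrationModel
#' @slot pureSpectra M x P matrix of fitted per-component spectra.
#' @slot componentKind per component: "analyte", "channel" or "residual".
#' @slot sourceChannel channel index behind each pseudo-component (NA for
#'   analytes and residual columns).
#' @export
setClass("CLSCalibration", contains = "CalibrationModel", representation(
  pureSpectra = "matrix",
  componentKind = "character",
  sourceChannel = "integer"
))

#' @rdname CalibrationModel
#' @slot r2 squared correlation of every channel with the target analyte.
#' @slot candidateOrder low-correlation channels in selection order.
#' @slot rmsecvCurve RMSECV for m = 0..mMax appended channels.
#' @slot chosenM number of channels actually appended.
#' @export
setClass("ACLSCalibration", contains = "CLSCalibration", representation(
  r2 = "numeric",
  candidateOrder = "integer",
  rmsecvCurve = "numeric",
  chosenM = "integer"
))

#' @rdname CalibrationModel
#' @slot coefficients length-P regression vector on centered spectra.
#' @slot intercept scalar offset returning predictions to original units.
#' @slot nComponents number of principal components / latent variables.
#' @slot loadings P x nComponents loading matrix.
#' @export
setClass("LatentCalibration", contains = "CalibrationModel", representation(
  coefficients = "numeric",
  intercept = "numeric",
  nComponents = "integer",
  loadings = "matrix"
))

#' SyntheticScenario: a fully seeded synthetic Raman study design
#'
#' Describes a reaction-monitoring Raman dataset: the wavenumber grid, the
#' batch layout, Gaussian/Lorentzian peak lists for the three analytes of a
#' sequential first-order reaction A -> B -> C, the kinetics, the unmodeled
#' interferents (extra spectral components, baseline drift, wavelength shift,
#' intensity nonlinearity), and the spectral noise level. Together with the
#' seed it fully determines the dataset produced by [generateDataset()].
#'
#' @slot name scenario label.
#' @slot axisStart,axisStop,axisStep wavenumber grid in 1/cm.
#' @slot samplesPerBatch integer vector, one entry per independent batch.
#' @slot analyteNames names of the three analytes (reactant, intermediate,
#'   product); the first is the target by convention.
#' @slot peaks list of three peak lists; each peak is
#'   `list(center=, width=, amplitude=, shape="gaussian"|"lorentzian")`.
#' @slot c0 initial reactant concentration (concentration units).
#' @slot k1,k2 first-order rate constants (per unit time), k1 != k2.
#' @slot batchKineticsSd lognormal sd of per-batch jitter on k1 and k2.
#' @slot batchC0Sd lognormal sd of per-batch jitter on the initial charge c0
#'   (batches are never charged perfectly identically; this also keeps the
#'   three analyte columns, which sum to the batch's c0, from being exactly
#'   collinear across the dataset).
#' @slot tMax duration of each batch (time units).
#' @slot timeExponent exponent of the within-batch sampling grid
#'   t_i = tMax * ((i-1)/(n-1))^timeExponent; values > 1 sample densely early,
#'   giving the uneven concentration coverage of a decelerating reaction.
#' @slot interferents list of interferent specs, each
#'   `list(kind=, magnitude=, ...)` with kinds "spectral-component"
#'   (extra peaks + a concentration profile), "baseline-drift" (per-sample
#'   quadratic baseline), "wavelength-shift" (per-sample axis shift in 1/cm),
#'   and "intensity-nonlinearity" (x -> x - beta * x^2).
#' @slot noiseSd standard deviation of i.i.d. Gaussian spectral noise.
#' @slot seed default random seed.
#' @aliases SyntheticScenario-class
#' @export
setClass("SyntheticScenario", representation(
  name = "character",
  axisStart = "numeric",
  axisStop = "numeric",
  axisStep = "numeric",
  samplesPerBatch = "integer",
  analyteNames = "character",
  peaks = "list",
  c0 = "numeric",
  k1 = "numeric",
  k2 = "numeric",
  batchKineticsSd = "numeric",
  batchC0Sd = "numeric",
  tMax = "numeric",
  timeExponent = "numeric",
  interferents = "list",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@axisStep <= 0) msg <- c(msg, "axisStep must be positive")
  if (object@axisStop <= object@axisStart) msg <- c(msg, "axisStop must exceed axisStart")
  if (any(object@samplesPerBatch < 2L)) msg <- c(msg, "each batch needs at least 2 samples")
  if (length(object@analyteNames) != 3L) msg <- c(msg, "exactly three analytes are modeled")
  if (length(object@peaks) != 3L) msg <- c(msg, "peaks must list one peak set per analyte")
  if (object@c0 <= 0) msg <- c(msg, "c0 must be positive")
  if (object@k1 <= 0 || object@k2 <= 0) msg <- c(msg, "rate constants must be positive")
  if (object@k1 == object@k2) msg <- c(msg, "k1 and k2 must differ (sequential kinetics)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})
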