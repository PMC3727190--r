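#' @import methods
NULL

#' Wavenumber axis of an object
#'
#' @param x a [RamanExperiment] or calibration model.
#' @return numeric vector of wavenumbers in 1/cm, strictly increasing.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Sample-by-channel intensity matrix
#'
#' @param x a [RamanExperiment].
#' @return L x P numeric matrix (samples in rows, channels in columns).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Known analyte concentration matrix
#'
#' @param x a [RamanExperiment].
#' @return L x M numeric matrix, one column per known analyte.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' Analyte names
#' @param x a [RamanExperiment].
#' @return character vector of analyte column names.
#' @export
setGeneric("analyteNames", function(x) standardGeneric("analyteNames"))

#' Batch (process run) assignment of samples
#' @param x a [RamanExperiment].
#' @return factor of batch ids, one per sample.
#' @export
setGeneric("batches", function(x) standardGeneric("batches"))

#' Predict the target analyte concentration from new spectra
#'
#' @param object a fitted calibration model.
#' @param newdata a [RamanExperiment] or an L x P intensity matrix on the
#'   model's wavenumber axis.
#' @param ... method-specific arguments; CLS-family models accept
#'   `full = TRUE` to return the complete predicted component matrix
#'   (pseudo-component columns are bookkeeping, never chemistry).
#' @return numeric vector of predicted target concentrations (original
#'   units), or the full predicted component matrix when `full = TRUE`.
#' @export
setGeneric("predictConcentration",
           function(object, newdata, ...) standardGeneric("predictConcentration"))

#' Fitted pure-component spectra of a CLS-family model
#' @param x a CLS-family calibration model.
#' @return M x P matrix of fitted per-component spectra.
#' @export
setGeneric("pureSpectra", function(x) standardGeneric("pureSpectra"))

#' Spectral channels appended as pseudo-components
#' @param x an ACLS calibration model.
#' @return integer vector of channel indices (into the wavenumber axis).
#' @export
setGeneric("augmentedChannels", function(x) standardGeneric("augmentedChannels"))

#' RMSECV-versus-augmentation-size curve
#' @param x an ACLS calibration model.
#' @return numeric vector; element m+1 is the leave-one-out RMSECV with m
#'   appended channels.
#' @export
setGeneric("rmsecvCurve", function(x) standardGeneric("rmsecvCurve"))
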