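#' Construct a RamanExperiment
#'
#' @param intensity L x P numeric matrix of spectral intensities, samples in
#'   rows and wavenumber channels in columns (the natural orientation of a
#'   delimited-text spectra table). Stored transposed, channels x samples, as
#'   the `"intensity"` assay.
#' @param wavenumber strictly increasing numeric vector of length P (1/cm).
#' @param concentrations L x M numeric matrix or data.frame of known analyte
#'   concentrations; column names are the analyte labels.
#' @param batch optional length-L vector of batch / process-run ids.
#' @param sampleIds optional length-L character vector of sample labels;
#'   defaults to rownames of `intensity` or `sample1..sampleL`.
#' @return a [RamanExperiment].
#' @examples
#' wn <- seq(400, 500, by = 10)
#' A <- matrix(runif(5 * length(wn)), nrow = 5)
#' C <- cbind(PA = runif(5))
#' re <- RamanExperiment(A, wn, C)
#' dim(intensities(re))
#' @export
RamanExperiment <- function(intensity, wavenumber, concentrations,
                            batch = NULL, sampleIds = NULL) {
  intensity <- as.matrix(intensity)
  .checkFiniteMatrix(intensity, "intensity")
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) < 2L) stop("wavenumber axis needs at least 2 channels")
  if (any(diff(wavenumber) <= 0)) stop("wavenumber axis must be strictly increasing")
  if (ncol(intensity) != length(wavenumber)) {
    stop("ncol(intensity) must equal length(wavenumber)")
  }
  L <- nrow(intensity)
  if (is.null(sampleIds)) {
    sampleIds <- rownames(intensity)
    if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(L))
  }
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
  conc <- as.matrix(concentrations)
  if (nrow(conc) != L) stop("concentrations must have one row per sample")
  .checkFiniteMatrix(conc, "concentrations")
  if (is.null(colnames(conc))) {
    colnames(conc) <- paste0("analyte", seq_len(ncol(conc)))
  }
  cd <- S4Vectors::DataFrame(conc, row.names = sampleIds, check.names = FALSE)
  if (!is.null(batch)) {
    if (length(batch) != L) stop("batch must have one entry per sample")
    cd$batch <- factor(batch)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(intensity = t(unname(intensity))),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumber),
    colData = cd
  )
  colnames(se) <- sampleIds
  rownames(se) <- as.character(wavenumber)
  obj <- methods::new("RamanExperiment", se)
  S4Vectors::metadata(obj)$analytes <- colnames(conc)
  methods::validObject(obj)
  obj
}

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "RamanExperiment", function(x) {
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber)
})

#' @rdname intensities
#' @export
setMethod("intensities", "RamanExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "intensity"))
})

#' @rdname concentrations
#' @export
setMethod("concentrations", "RamanExperiment", function(x) {
  an <- analyteNames(x)
  cd <- SummarizedExperiment::colData(x)
  m <- as.matrix(as.data.frame(cd[, an, drop = FALSE]))
  rownames(m) <- colnames(x)
  colnames(m) <- an
  m
})

#' @rdname analyteNames
#' @export
setMethod("analyteNames", "RamanExperiment", function(x) {
  an <- S4Vectors::metadata(x)$analytes
  if (is.null(an)) colnames(SummarizedExperiment::colData(x)) else an
})

#' @rdname batches
#' @export
setMethod("batches", "RamanExperiment", function(x) {
  b <- SummarizedExperiment::colData(x)$batch
  if (is.null(b)) factor(rep(1L, ncol(x))) else factor(b)
})

setMethod("show", "RamanExperiment", function(object) {
  w <- wavenumbers(object)
  cat("RamanExperiment:", ncol(object), "samples x", nrow(object), "channels\n")
  cat("  wavenumber axis:", w[1L], "-", w[length(w)], "1/cm\n")
  cat("  analytes:", paste(analyteNames(object), collapse = ", "), "\n")
  b <- SummarizedExperiment::colData(object)$batch
  if (!is.null(b)) cat("  batches:", nlevels(factor(b)), "\n")
  invisible(NULL)
})
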