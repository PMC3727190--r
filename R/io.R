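# Delimited-text I/O. Datasets travel as two CSV tables sharing a sample-id
# column: a spectra table whose header row is the numeric wavenumber axis,
# and a concentration table whose header names the analytes. Readers reject
# malformed input rather than silently coercing it.

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.checkNumericColumns <- function(df, what) {
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric cells in ", what, " column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  }
}

#' Read a dataset from delimited-text tables
#'
#' @param spectraPath CSV whose first column is the sample id and whose
#'   remaining header fields are the (numeric, strictly increasing)
#'   wavenumbers.
#' @param concPath CSV whose first column is the sample id and whose
#'   remaining columns are analyte concentrations; an optional `batch`
#'   column is kept as the batch assignment. Rows are aligned to the spectra
#'   table by sample id, so row order may differ between the files.
#' @return a [RamanExperiment].
#' @seealso [writeDataset()]
#' @export
readDataset <- function(spectraPath, concPath) {
  sp <- .readTable(spectraPath)
  co <- .readTable(concPath)
  idsS <- as.character(sp[[1L]])
  idsC <- as.character(co[[1L]])
  if (anyDuplicated(idsS)) stop("duplicate sample id in spectra table")
  if (anyDuplicated(idsC)) stop("duplicate sample id in concentration table")
  if (!setequal(idsS, idsC)) {
    stop("mismatched sample ids between spectra and concentration tables")
  }
  wn <- suppressWarnings(as.numeric(colnames(sp)[-1L]))
  if (any(is.na(wn))) stop("spectra header must be numeric wavenumbers")
  if (any(diff(wn) <= 0)) stop("wavenumbers in spectra header must be strictly increasing")
  spd <- sp[-1L]
  .checkNumericColumns(spd, "spectra")
  co <- co[match(idsS, idsC), , drop = FALSE]
  batch <- NULL
  if ("batch" %in% colnames(co)) {
    batch <- co$batch
    co <- co[setdiff(colnames(co), "batch")]
  }
  cod <- co[-1L]
  .checkNumericColumns(cod, "concentration")
  RamanExperiment(as.matrix(spd), wn, as.matrix(cod), batch = batch,
                  sampleIds = idsS)
}

#' Write a dataset as delimited-text tables
#'
#' Writes the two CSV tables read back by [readDataset()], at full floating
#' point precision.
#'
#' @param re a [RamanExperiment].
#' @param spectraPath,concPath output paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(re, spectraPath, concPath) {
  A <- intensities(re)
  sp <- data.frame(sample = colnames(re), A, check.names = FALSE)
  colnames(sp)[-1L] <- as.character(wavenumbers(re))
  utils::write.csv(sp, spectraPath, row.names = FALSE, quote = FALSE)
  C <- concentrations(re)
  co <- data.frame(sample = colnames(re), C, check.names = FALSE)
  b <- SummarizedExperiment::colData(re)$batch
  if (!is.null(b)) co$batch <- as.character(b)
  utils::write.csv(co, concPath, row.names = FALSE, quote = FALSE)
  invisible(c(spectraPath, concPath))
}

#' Write a model comparison table
#'
#' Delimited-text rendering of a [compareModels()] result with the columns
#' `method, R2, RMSEP, p_vs_previous, RMSECV`, numbers at 5 significant
#' digits.
#'
#' @param tab data.frame from [compareModels()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeComparisonTable <- function(tab, path) {
  if (nrow(tab) == 0L) stop("empty method list: nothing to write")
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 5L))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a comparison table written by [writeComparisonTable()]
#' @param path CSV path.
#' @return data.frame.
#' @export
readComparisonTable <- function(path) {
  .readTable(path)
}

# ---- scenario config -------------------------------------------------------

.scenarioSlots <- c("name", "axisStart", "axisStop", "axisStep",
                    "samplesPerBatch", "analyteNames", "peaks", "c0", "k1",
                    "k2", "batchKineticsSd", "batchC0Sd", "tMax", "timeExponent",
                    "interferents", "noiseSd", "seed")

#' Serialize / restore a scenario as a plain-text config
#'
#' A [SyntheticScenario] round-trips through a YAML file (keys mirror the
#' class slots), so study designs can be versioned and passed to the command
#' line.
#'
#' @param scenario a [SyntheticScenario].
#' @param path file path.
#' @return `writeScenario` returns the path invisibly; `readScenario` returns
#'   the restored [SyntheticScenario].
#' @export
writeScenario <- function(scenario, path) {
  vals <- lapply(.scenarioSlots, function(s) methods::slot(scenario, s))
  names(vals) <- .scenarioSlots
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  missing <- setdiff(.scenarioSlots, names(vals))
  if (length(missing)) {
    stop("scenario config is missing field(s): ", paste(missing, collapse = ", "))
  }
  vals$samplesPerBatch <- as.integer(vals$samplesPerBatch)
  vals$seed <- as.integer(vals$seed)
  vals$analyteNames <- as.character(vals$analyteNames)
  do.call(syntheticScenario, vals[.scenarioSlots])
}
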