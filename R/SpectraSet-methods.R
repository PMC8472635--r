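#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples by wavenumbers.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1. If supplied
#'   ascending, the axis and the absorbance columns are reordered to the
#'   descending instrument convention.
#' @param meta data.frame with one row per spectrum and columns `sample_id`,
#'   `cow_id`, `dim`, `parity`, `replicate` (extra columns are kept).
#' @return a validated [SpectraSet-class].
#' @examples
#' wn <- seq(1800, 1700, by = -6)
#' x <- matrix(rnorm(3 * length(wn)), 3)
#' m <- data.frame(sample_id = paste0("s", 1:3), cow_id = "c1",
#'                 dim = c(5, 7, 9), parity = 1, replicate = 1)
#' s <- SpectraSet(x, wn, m)
#' @export
SpectraSet <- function(absorbance, wavenumbers, meta) {
  absorbance <- as.matrix(absorbance)
  if (!is.numeric(absorbance)) stop("absorbance must be numeric")
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers))
    stop(sprintf("absorbance has %d columns but %d wavenumbers were given",
                 ncol(absorbance), length(wavenumbers)))
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(absorbance))
    stop(sprintf("metadata has %d rows but the spectra table has %d rows",
                 nrow(meta), nrow(absorbance)))
  if (length(wavenumbers) > 1L && wavenumbers[1L] < wavenumbers[2L]) {
    o <- order(wavenumbers, decreasing = TRUE)
    wavenumbers <- wavenumbers[o]
    absorbance <- absorbance[, o, drop = FALSE]
  }
  dimnames(absorbance) <- list(as.character(meta$sample_id), NULL)
  meta$dim <- as.integer(meta$dim)
  meta$parity <- as.integer(meta$parity)
  meta$replicate <- as.integer(meta$replicate)
  cd <- DataFrame(meta)
  rownames(cd) <- meta$sample_id
  se <- SummarizedExperiment(
    assays = list(absorbance = t(absorbance)),
    rowData = DataFrame(wavenumber = wavenumbers),
    colData = cd)
  new("SpectraSet", se)
}

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  as.numeric(rowData(x)$wavenumber))

#' @rdname absorbance
#' @export
setMethod("absorbance", "SpectraSet", function(x) {
  m <- t(assay(x, "absorbance"))
  dimnames(m) <- list(colData(x)$sample_id,
                      format(rowData(x)$wavenumber, trim = TRUE))
  m
})

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "SpectraSet", function(x) {
  df <- as.data.frame(colData(x))
  rownames(df) <- NULL
  df
})

#' @rdname nSamples
#' @export
setMethod("nSamples", "SpectraSet", function(x) ncol(x))

#' @rdname provenance
#' @export
setMethod("provenance", "SpectraSet", function(x) metadata(x)$provenance)

#' @rdname provenance
#' @export
setMethod("provenance<-", "SpectraSet", function(x, value) {
  metadata(x)$provenance <- value
  x
})

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cd <- colData(object)
  cat("SpectraSet with", ncol(object), "spectra x", length(wn), "wavenumbers\n")
  if (length(wn))
    cat(sprintf("  axis: %.1f .. %.1f cm-1 (descending)\n", wn[1L], wn[length(wn)]))
  if (nrow(cd)) {
    cat("  cows:", length(unique(cd$cow_id)),
        " DIM range:", paste(range(cd$dim), collapse = "-"), "\n")
    if (!is.null(cd$stage))
      cat("  stage labels:", paste(names(table(cd$stage)),
          table(cd$stage), sep = "=", collapse = " "), "\n")
  }
  if (!is.null(metadata(object)$provenance))
    cat("  preprocessed: yes (provenance attached)\n")
  invisible(NULL)
})

setMethod("show", "GroupedSplit", function(object) {
  sz <- vapply(object@segments, function(s) length(s$validation), 1L)
  cat("GroupedSplit:", length(object@segments), "segments by",
      object@groupKey, "\n  validation sizes:",
      paste(range(sz), collapse = "-"), "\n")
  invisible(NULL)
})

setMethod("show", "PCAModel", function(object) {
  k <- ncol(object@scores)
  ef <- object@explainedFraction
  cat("PCAModel:", k, "components of", length(ef), "\n  explained:",
      paste(sprintf("%.1f%%", 100 * ef[seq_len(min(k, 5))]), collapse = " "),
      "\n")
  invisible(NULL)
})

setMethod("show", "PLSRModel", function(object) {
  cat("PLSRModel for", object@analyte, "-", object@nLv, "LV,",
      length(object@coefficients), "variables\n")
  if (length(object@metrics)) {
    m <- object@metrics
    if (!is.null(m$rmsecv)) cat(sprintf("  RMSECV %.4g", m$rmsecv))
    if (!is.null(m$rmsep)) cat(sprintf("  RMSEP %.4g", m$rmsep))
    if (!is.null(m$r2)) cat(sprintf("  R2 %.3f", m$r2))
    cat("\n")
  }
  invisible(NULL)
})

setMethod("show", "SPLSDAModel", function(object) {
  cat("SPLSDAModel:", paste(object@classCode, collapse = " vs "), "-",
      object@nLv, "LV, sparsity",
      paste(unique(object@sparsity), collapse = "/"), "\n  selected",
      sum(object@selectedMask), "of", length(object@selectedMask),
      "variables")
  if (is.finite(object@cvAccuracy))
    cat(sprintf(", CV accuracy %.3f", object@cvAccuracy))
  cat("\n")
  invisible(NULL)
})
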