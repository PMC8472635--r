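#' Read spectra and sample metadata from CSV
#'
#' The spectra file is a wide table: first header cell `sample_id`, remaining
#' header cells wavenumbers in cm^-1, one row per spectrum. The metadata file
#' has columns `sample_id`, `cow_id`, `dim`, `parity`, `replicate`, one row per
#' spectra row. Ascending wavenumber files are reordered to the descending
#' instrument convention with the absorbance columns permuted consistently.
#'
#' @param spectraPath,metaPath CSV file paths.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(spectraPath, metaPath) {
  sp <- data.table::fread(spectraPath, header = TRUE, data.table = FALSE)
  .stopIf(colnames(sp)[1L] != "sample_id",
          "spectra file must start with a 'sample_id' column, found '%s'",
          colnames(sp)[1L])
  wn <- suppressWarnings(as.numeric(colnames(sp)[-1L]))
  .stopIf(anyNA(wn), "non-numeric wavenumber header cell(s): %s",
          paste(colnames(sp)[-1L][is.na(wn)][1:3], collapse = ", "))
  x <- as.matrix(sp[, -1L, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(!vapply(sp[-1L], is.numeric, TRUE))[1L]
    nonnum <- which(is.na(suppressWarnings(as.numeric(sp[[bad + 1L]]))))[1L]
    stop(sprintf("non-numeric absorbance cell at row %d, column '%s'",
                 nonnum, colnames(sp)[bad + 1L]), call. = FALSE)
  }
  meta <- data.table::fread(metaPath, header = TRUE, data.table = FALSE)
  .stopIf(nrow(meta) != nrow(sp),
          "metadata has %d rows but the spectra table has %d rows",
          nrow(meta), nrow(sp))
  o <- match(sp$sample_id, meta$sample_id)
  if (!anyNA(o)) meta <- meta[o, , drop = FALSE]
  SpectraSet(x, wn, meta)
}

#' Write a SpectraSet to the spectra/metadata CSV pair
#'
#' @param s a [SpectraSet-class].
#' @param spectraPath,metaPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeSpectra <- function(s, spectraPath, metaPath) {
  x <- absorbance(s)
  df <- data.frame(sample_id = sampleMeta(s)$sample_id, x,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", format(wavenumbers(s), trim = TRUE))
  data.table::fwrite(df, spectraPath)
  data.table::fwrite(sampleMeta(s), metaPath)
  invisible(c(spectraPath, metaPath))
}

#' Read a cow-level table (parity and blood BHB)
#'
#' Expects columns `cow_id`, `parity`, `bhb_ng_per_ml`; derives the ketosis
#' flag and BHB tier via [cowRecords()].
#' @param path CSV path.
#' @return data.frame of cow records.
#' @export
readCows <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("cow_id", "parity", "bhb_ng_per_ml")
  miss <- setdiff(need, colnames(df))
  .stopIf(length(miss) > 0, "cow table lacks column(s): %s",
          paste(miss, collapse = ", "))
  cowRecords(df)
}

#' Read a fatty-acid feature table
#'
#' Columns: `sample_id` plus the nine fatty-acid features (percent of total
#' fatty acids): C10:0, C14:0, C16:0, C18:0, C18:1cis9, CLA, SAT, MUFA, PUFA.
#' @param path CSV path.
#' @return data.frame, first column `sample_id`.
#' @export
readFA <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  .stopIf(colnames(df)[1L] != "sample_id",
          "FA table must start with a 'sample_id' column")
  miss <- setdiff(faFeatureNames(), colnames(df))
  .stopIf(length(miss) > 0, "FA table lacks feature(s): %s",
          paste(miss, collapse = ", "))
  df
}

#' Names of the nine fatty-acid features
#' @return character vector in canonical order.
#' @export
faFeatureNames <- function() {
  c("C10:0", "C14:0", "C16:0", "C18:0", "C18:1cis9",
    "CLA", "SAT", "MUFA", "PUFA")
}
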