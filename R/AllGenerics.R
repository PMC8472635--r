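#' Wavenumber axis of a spectral object
#' @param x a [SpectraSet-class]
#' @return numeric vector of wavenumbers in cm^-1, strictly descending.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Absorbance matrix, samples as rows
#'
#' Returns the spectra in the samples-by-wavenumbers orientation used
#' throughout the analysis functions (internally the object stores the
#' transpose, following the SummarizedExperiment convention).
#' @param x a [SpectraSet-class]
#' @return numeric matrix, `nSamples(x)` by `length(wavenumbers(x))`, with
#'   sample ids as row names and wavenumbers as column names.
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Per-sample metadata as a data.frame
#' @param x a [SpectraSet-class]
#' @return data.frame with one row per sample.
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' Number of samples in a spectral object
#' @param x a [SpectraSet-class]
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Preprocessing provenance attached to a spectral object
#'
#' After [preprocessPipeline()] this records the preprocessing spec and the
#' frozen EMSC reference so prediction-time data can be treated identically.
#' @param x a [SpectraSet-class]
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @param value a list
#' @export
setGeneric("provenance<-", function(x, value) standardGeneric("provenance<-"))

#' Group-wise averaging of samples
#'
#' Averages rows (samples) of a spectral set or a per-sample feature table by
#' the levels of a metadata key, returning one averaged row per level in
#' ascending key order.
#' @param x a [SpectraSet-class] or a data.frame of per-sample features whose
#'   first column is `sample_id`.
#' @param key metadata field to average over: `"dim"`, `"parity"` or
#'   `"cow_id"`.
#' @param meta for the data.frame method, the sample metadata table.
#' @return data.frame whose first column is the key level and remaining
#'   columns are the averaged variables.
#' @export
setGeneric("averageBy", function(x, key, meta = NULL) standardGeneric("averageBy"))
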