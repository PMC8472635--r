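#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData colData<-
NULL

#' SpectraSet: FTIR spectra with per-sample metadata
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"absorbance"` assay. Rows are wavenumbers (strictly descending, the
#' instrument convention), columns are samples. Sample metadata (`cow_id`,
#' `dim` days-in-milk, `parity`, `replicate`, and the derived `stage` and
#' `parity_group` labels) live in `colData`; preprocessing provenance (the
#' preprocessing spec and the frozen EMSC reference) lives in `metadata`.
#'
#' Validity enforces: strictly decreasing wavenumber axis, numeric absorbance,
#' metadata row count equal to the number of spectra, and no duplicated
#' (`cow_id`, `dim`, `replicate`) triple. Finiteness of the absorbance values
#' is deliberately *not* part of validity: corrupted spectra must be
#' representable so that [qualityCheck()] can find and remove them.
#'
#' @seealso [SpectraSet()] for construction, [absorbance()], [wavenumbers()],
#'   [sampleMeta()] for access.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is missing")
  wn <- rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData column 'wavenumber' is missing")
  } else {
    if (!is.numeric(wn)) msg <- c(msg, "wavenumbers must be numeric")
    if (length(wn) > 1L && any(diff(wn) >= 0))
      msg <- c(msg, "wavenumber axis must be strictly decreasing")
  }
  cd <- colData(object)
  need <- c("sample_id", "cow_id", "dim", "parity", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(cd)) {
    key <- paste(cd$cow_id, cd$dim, cd$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      d <- cd[duplicated(key), , drop = FALSE][1L, ]
      msg <- c(msg, sprintf(
        "duplicate (cow_id, dim, replicate) triple: (%s, %s, %s)",
        d$cow_id, d$dim, d$replicate))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Grouped cross-validation split
#'
#' Holds the train/validation index sets of a grouped (or random segmented)
#' cross-validation. Validation sets are pairwise disjoint and tile the sample
#' index set; when `groupKey` names a metadata field, no group ever appears on
#' both sides of a segment.
#'
#' @slot segments list of `list(train=, validation=)` integer index vectors.
#' @slot groupKey character; metadata field used for grouping, or `"random"`.
#' @export
setClass("GroupedSplit",
  representation(segments = "list", groupKey = "character"))

setValidity("GroupedSplit", function(object) {
  segs <- object@segments
  if (!length(segs)) return("no segments")
  val <- unlist(lapply(segs, `[[`, "validation"))
  if (anyDuplicated(val)) return("validation sets overlap")
  for (s in segs)
    if (length(intersect(s$train, s$validation)))
      return("a segment's train and validation sets intersect")
  TRUE
})

#' Principal component analysis result
#'
#' Column-mean-centred PCA fitted by singular value decomposition. Loadings are
#' stored components-by-variables with orthonormal rows; the sign convention is
#' that each loading's largest-magnitude element is positive, so results are
#' deterministic.
#'
#' @slot scores n-by-k score matrix (U S).
#' @slot loadings k-by-p loading matrix (rows of V^T).
#' @slot explainedFraction fraction of total variance per component, for all
#'   components (non-increasing, sums to 1 up to rank).
#' @slot center column means removed before decomposition.
#' @export
setClass("PCAModel",
  representation(scores = "matrix", loadings = "matrix",
                 explainedFraction = "numeric", center = "numeric"))

#' Single-response partial least squares regression model
#'
#' A PLS1 model fitted by the NIPALS recursion (computed through its Gram-matrix
#' kernel form). Stores per-LV weights/loadings so predictions can be produced
#' at any nested number of latent variables, the assembled regression vector at
#' `nLv`, and the validation metrics collected during model selection.
#'
#' @slot analyte response name (e.g. a fatty-acid feature).
#' @slot nLv number of latent variables in the assembled coefficients.
#' @slot coefficients regression vector (length p) for centred X.
#' @slot intercept scalar intercept on the original scale.
#' @slot xMeans,yMean centring constants.
#' @slot weights,loadingsX p-by-A weight (W) and X-loading (P) matrices.
#' @slot scoreCoef p-by-A matrix R = W (P'W)^-1 mapping centred X to scores.
#' @slot q per-LV regression of y on scores.
#' @slot metrics named list of validation metrics (rmsecv curve, rmsep, r2...).
#' @slot provenance preprocessing provenance carried from the training data.
#' @export
setClass("PLSRModel",
  representation(analyte = "character", nLv = "integer",
                 coefficients = "numeric", intercept = "numeric",
                 xMeans = "numeric", yMean = "numeric",
                 weights = "matrix", loadingsX = "matrix",
                 scoreCoef = "matrix", q = "numeric",
                 metrics = "list", provenance = "list"))

#' Sparse PLS discriminant analysis model
#'
#' Two-class PLS-DA in which each latent variable's weight vector is
#' hard-thresholded to its top (1 - sparsity) fraction of entries by absolute
#' value (with a floor of one retained variable), then renormalised. The class
#' is predicted by thresholding the predicted 0/1 dummy response.
#'
#' @slot nLv number of latent variables.
#' @slot sparsity per-LV sparsity levels in `[0, 1)`.
#' @slot classCode two class labels; first maps to 0, second to 1.
#' @slot threshold decision threshold on the predicted dummy (default 0.5).
#' @slot selectedMask logical, union of nonzero weights across LVs.
#' @slot cvAccuracy cross-validated accuracy at the selected grid point (NA if
#'   the model was fitted directly).
#' @slot gridAccuracy LV-by-sparsity CV accuracy matrix from optimisation.
#' @slot weights,loadingsX,scoreCoef,q,coefficients,intercept,xMeans,yMean as
#'   in [PLSRModel-class].
#' @slot provenance preprocessing provenance carried from the training data.
#' @export
setClass("SPLSDAModel",
  representation(nLv = "integer", sparsity = "numeric",
                 classCode = "character", threshold = "numeric",
                 selectedMask = "logical", cvAccuracy = "numeric",
                 gridAccuracy = "matrix",
                 coefficients = "numeric", intercept = "numeric",
                 xMeans = "numeric", yMean = "numeric",
                 weights = "matrix", loadingsX = "matrix",
                 scoreCoef = "matrix", q = "numeric",
                 provenance = "list"))
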