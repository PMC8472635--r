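#' Filter samples by days in milk
#'
#' Retains exactly the samples with `low <= dim <= high`, preserving order.
#' The conventional study window is DIM 5 to 100: samples collected before
#' day 5 or after day 100 are dropped.
#'
#' @param s a [SpectraSet-class].
#' @param low,high inclusive DIM bounds.
#' @return the filtered [SpectraSet-class]; a warning (not an error) is raised
#'   if nothing remains.
#' @export
filterDIM <- function(s, low = 5L, high = 100L) {
  .stopIf(low > high, "low (%s) must be <= high (%s)", low, high)
  keep <- which(colData(s)$dim >= low & colData(s)$dim <= high)
  if (!length(keep)) warning("filterDIM removed every sample")
  s[, keep]
}

#' Label lactation stage and parity group
#'
#' Adds the derived factors `stage` (DIM1 for 5 <= DIM <= 50, DIM2 for
#' 50 < DIM <= 100) and `parity_group` (PAR1, PAR2, PARgt2 for parity > 2)
#' to the sample metadata.
#'
#' @param s a [SpectraSet-class] with DIM values inside the study window.
#' @return the labelled [SpectraSet-class].
#' @export
labelStageParity <- function(s) {
  cd <- colData(s)
  .stopIf(any(cd$parity < 1L | cd$parity > 6L),
          "parity outside 1-6 found (value %s)",
          cd$parity[which(cd$parity < 1L | cd$parity > 6L)][1L])
  cd$stage <- factor(ifelse(cd$dim <= 50L, "DIM1", "DIM2"),
                     levels = c("DIM1", "DIM2"))
  cd$parity_group <- factor(
    ifelse(cd$parity > 2L, "PARgt2", paste0("PAR", cd$parity)),
    levels = c("PAR1", "PAR2", "PARgt2"))
  colData(s) <- cd
  s
}

#' Robust spectral quality check
#'
#' Flags a spectrum if (a) any absorbance value is non-finite, or (b) its
#' Pearson correlation with the set's median spectrum falls below the robust
#' lower bound `median(r) - zThreshold * mad(r)` (strict inequality). This is
#' a simple, distribution-free criterion for gross outliers; the threshold is
#' configurable.
#'
#' @param s a [SpectraSet-class] with at least 3 samples.
#' @param zThreshold robust z cut-off (default 3.5).
#' @return `list(spectra = cleaned SpectraSet, rejected = character ids)`.
#' @export
qualityCheck <- function(s, zThreshold = 3.5) {
  .stopIf(ncol(s) < 3L, "quality check needs at least 3 samples, got %d", ncol(s))
  x <- absorbance(s)
  bad <- !apply(is.finite(x), 1L, all)
  medSpec <- apply(x[!bad, , drop = FALSE], 2L, stats::median)
  r <- rep(NA_real_, nrow(x))
  ok <- which(!bad)
  r[ok] <- suppressWarnings(
    as.numeric(stats::cor(t(x[ok, , drop = FALSE]), medSpec)))
  bound <- stats::median(r, na.rm = TRUE) -
    zThreshold * stats::mad(r, na.rm = TRUE)
  flag <- bad | is.na(r) | r < bound
  .stopIf(all(flag), "quality check rejected every sample; threshold unusable")
  ids <- sampleMeta(s)$sample_id
  list(spectra = s[, which(!flag)], rejected = ids[flag])
}

#' Average replicate spectra
#'
#' Collapses replicates sharing a (cow_id, dim) pair to their arithmetic mean;
#' singleton groups pass through unchanged. Intended to run *after* spectral
#' preprocessing. The replicate field of the result is set to 0.
#'
#' @param s a [SpectraSet-class].
#' @return a [SpectraSet-class] with one spectrum per (cow_id, dim).
#' @export
averageReplicates <- function(s) {
  cd <- as.data.frame(colData(s))
  key <- paste(cd$cow_id, cd$dim, sep = "\r")
  if (!anyDuplicated(key)) {
    colData(s)$replicate <- 0L
    return(s)
  }
  x <- absorbance(s)
  g <- factor(key, levels = unique(key))
  xm <- rowsum(x, g, reorder = FALSE) / as.vector(table(g))
  first <- !duplicated(key)
  meta <- cd[first, , drop = FALSE]
  meta$replicate <- 0L
  meta$sample_id <- sprintf("%s_d%03d", meta$cow_id, meta$dim)
  out <- SpectraSet(xm, wavenumbers(s), meta)
  metadata(out) <- metadata(s)
  out
}

#' Derive cow-level ketosis status from blood BHB
#'
#' A cow is classed as experiencing subclinical ketosis when its blood
#' beta-hydroxybutyrate exceeds 1.0 ng/mL (strict inequality; a cow at exactly
#' 1.0 is normal). The tier splits the ketotic cows at 2.0 ng/mL:
#' normal `<= 1.0`, mid `(1.0, 2.0]`, high `> 2.0`.
#'
#' @param cows data.frame with columns `cow_id`, `parity`, `bhb_ng_per_ml`.
#' @return the same data.frame with logical `ketosis` and factor `tier` added.
#' @export
cowRecords <- function(cows) {
  cows <- as.data.frame(cows)
  .stopIf(any(cows$bhb_ng_per_ml < 0), "negative BHB concentration")
  cows$ketosis <- cows$bhb_ng_per_ml > 1.0
  cows$tier <- cut(cows$bhb_ng_per_ml, c(-Inf, 1.0, 2.0, Inf),
                   labels = c("normal", "mid", "high"))
  cows
}

#' @rdname averageBy
#' @export
setMethod("averageBy", "SpectraSet", function(x, key, meta = NULL) {
  .stopIf(!key %in% c("dim", "parity", "cow_id"),
          "key must be one of dim, parity, cow_id, got '%s'", key)
  cd <- as.data.frame(colData(x))
  lev <- sort(unique(cd[[key]]))
  g <- factor(cd[[key]], levels = lev)
  xm <- rowsum(absorbance(x), g, reorder = TRUE) / as.vector(table(g))
  out <- data.frame(lev, xm, check.names = FALSE)
  colnames(out) <- c(key, format(wavenumbers(x), trim = TRUE))
  rownames(out) <- NULL
  out
})

#' @rdname averageBy
#' @export
setMethod("averageBy", "data.frame", function(x, key, meta = NULL) {
  .stopIf(is.null(meta), "meta is required when averaging a feature table")
  .stopIf(colnames(x)[1L] != "sample_id",
          "feature table must start with a 'sample_id' column")
  m <- meta[match(x$sample_id, meta$sample_id), , drop = FALSE]
  lev <- sort(unique(m[[key]]))
  g <- factor(m[[key]], levels = lev)
  v <- as.matrix(x[, -1L, drop = FALSE])
  xm <- rowsum(v, g, reorder = TRUE) / as.vector(table(g))
  out <- data.frame(lev, xm, check.names = FALSE)
  colnames(out) <- c(key, colnames(x)[-1L])
  rownames(out) <- NULL
  out
})
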