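#' Preprocessing specification
#'
#' Bundles the parameters of the standard dry-film FTIR preprocessing chain:
#' Savitzky-Golay second derivative (window 13 points, polynomial degree 2),
#' wavenumber-region selection (3200-2800 and 1800-600 cm^-1, inclusive), and
#' EMSC normalisation with linear and quadratic baseline terms against the
#' mean spectrum of the set (or a frozen reference vector at prediction time).
#'
#' @param sgWindow odd window length in points (> `sgPolyorder`).
#' @param sgPolyorder polynomial degree of the local fit.
#' @param emscTerms polynomial degree of the EMSC baseline (2 = linear +
#'   quadratic).
#' @param regions list of inclusive wavenumber intervals to retain.
#' @param reference `"mean"` or a numeric reference spectrum on the processed
#'   axis (used to freeze the EMSC reference for prediction-time data).
#' @return an object of class `"PreprocessSpec"` (a list).
#' @export
preprocessSpec <- function(sgWindow = 13L, sgPolyorder = 2L, emscTerms = 2L,
                           regions = list(c(3200, 2800), c(1800, 600)),
                           reference = "mean") {
  .stopIf(sgWindow %% 2L == 0L, "sgWindow must be odd, got %d", sgWindow)
  .stopIf(sgWindow <= sgPolyorder, "sgWindow must exceed sgPolyorder")
  .stopIf(sgPolyorder < 2L, "second-derivative filter needs polyorder >= 2")
  regions <- lapply(regions, function(r) sort(as.numeric(r)))
  if (length(regions) > 1L) {
    b <- do.call(rbind, regions)
    b <- b[order(b[, 1L]), , drop = FALSE]
    .stopIf(any(b[-1L, 1L] <= b[-nrow(b), 2L]), "regions must not overlap")
  }
  structure(list(sgWindow = as.integer(sgWindow),
                 sgPolyorder = as.integer(sgPolyorder),
                 sgDeriv = 2L, emscTerms = as.integer(emscTerms),
                 regions = regions, reference = reference),
            class = "PreprocessSpec")
}

# Savitzky-Golay convolution coefficients for the m-th derivative at the
# window centre: least-squares fit of a degree-`polyorder` polynomial over
# offsets -h..h, in index units (caller rescales by the point spacing).
.sgCoef <- function(window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  i <- seq(-h, h)
  V <- outer(i, 0:polyorder, `^`)
  Ci <- solve(crossprod(V), t(V))      # (polyorder+1) x window
  factorial(deriv) * Ci[deriv + 1L, ]
}

#' Savitzky-Golay second derivative of a spectral set
#'
#' Replaces each spectrum by its second derivative in absorbance per
#' (cm^-1)^2, computed by local least-squares polynomial fitting on a uniform
#' wavenumber grid. The half-window of points at each end of the axis is
#' dropped rather than extrapolated, so no curvature is fabricated at the
#' spectrum ends.
#'
#' @param s a [SpectraSet-class] on a uniform axis (relative tolerance 1e-6).
#' @param window odd window length in points (default 13).
#' @param polyorder polynomial degree (default 2).
#' @return a [SpectraSet-class] on the shortened axis.
#' @export
sgSecondDerivative <- function(s, window = 13L, polyorder = 2L) {
  wn <- wavenumbers(s)
  .stopIf(length(wn) < window,
          "spectrum length %d shorter than SG window %d", length(wn), window)
  .stopIf(window %% 2L == 0L || window <= polyorder,
          "window must be odd and exceed polyorder")
  d <- diff(wn)
  spacing <- mean(abs(d))
  .stopIf(max(abs(abs(d) - spacing)) > 1e-6 * spacing,
          "wavenumber axis is not uniformly spaced")
  cf <- .sgCoef(window, polyorder, 2L) / spacing^2
  x <- absorbance(s)
  p <- ncol(x); h <- (window - 1L) %/% 2L
  nOut <- p - window + 1L
  out <- matrix(0, nrow(x), nOut)
  for (j in seq_len(window))
    out <- out + cf[j] * x[, j:(j + nOut - 1L), drop = FALSE]
  res <- SpectraSet(out, wn[(h + 1L):(p - h)], sampleMeta(s))
  metadata(res) <- metadata(s)
  res
}

# Least-squares EMSC decomposition of samples-as-rows matrix `x` against
# reference `m`: x_i ~ a + b*m + d*nu + e*nu^2 + ... (nu = axis mapped to
# [-1,1]). Returns list(corrected, fits). Plain (non-orthogonalised) basis.
.emscFitMatrix <- function(x, wn, reference, degree = 2L) {
  p <- length(wn)
  nu <- if (max(wn) > min(wn)) 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
        else rep(0, p)
  B <- outer(nu, seq_len(degree), `^`)            # baseline terms nu^1..nu^d
  D <- cbind(ref = reference, const = 1, B)
  qrD <- qr(D)
  .stopIf(qrD$rank < ncol(D), "singular EMSC design (reference collinear with baseline)")
  coef <- qr.coef(qrD, t(x))                      # (2+degree) x n
  b <- coef["ref", ]
  baseline <- D[, -1L, drop = FALSE] %*% coef[-1L, , drop = FALSE]
  corrected <- (x - t(baseline)) / b
  resid <- t(x) - D %*% coef
  fits <- data.frame(a = coef["const", ], b = b,
                     d = if (degree >= 1) coef[3L, ] else 0,
                     e = if (degree >= 2) coef[4L, ] else 0,
                     residual_norm = sqrt(colSums(resid^2)))
  list(corrected = corrected, fits = fits)
}

#' Extended multiplicative signal correction
#'
#' Fits each spectrum z as `a + b*m + d*nu + e*nu^2` (for `degree = 2`), where
#' `m` is the reference spectrum and `nu` the wavenumber axis affinely mapped
#' to \[-1, 1\], by ordinary least squares; the corrected spectrum is
#' `(z - a - d*nu - e*nu^2)/b`. The baseline polynomials are not
#' orthogonalised against the reference. Spectra nearly orthogonal to the
#' reference (|b| < 1e-8) are excluded with a warning.
#'
#' @param s a [SpectraSet-class].
#' @param reference `"mean"` (the mean spectrum of `s`) or a numeric spectrum
#'   on the same axis.
#' @param degree polynomial degree of the baseline terms (default 2).
#' @return `list(spectra = corrected SpectraSet, fits = data.frame)` with one
#'   fit row (a, b, d, e, residual_norm) per retained spectrum. The reference
#'   used is stored in the result's provenance.
#' @export
emscCorrect <- function(s, reference = "mean", degree = 2L) {
  x <- absorbance(s)
  wn <- wavenumbers(s)
  m <- if (identical(reference, "mean")) colMeans(x) else as.numeric(reference)
  .stopIf(length(m) != length(wn),
          "reference length %d does not match axis length %d",
          length(m), length(wn))
  fit <- .emscFitMatrix(x, wn, m, degree)
  bad <- abs(fit$fits$b) < 1e-8
  if (any(bad)) {
    warning(sprintf(
      "%d spectrum/spectra near-orthogonal to the EMSC reference excluded: %s",
      sum(bad), paste(sampleMeta(s)$sample_id[bad], collapse = ", ")))
  }
  keep <- which(!bad)
  out <- SpectraSet(fit$corrected[keep, , drop = FALSE], wn,
                    sampleMeta(s)[keep, , drop = FALSE])
  metadata(out) <- metadata(s)
  prov <- provenance(out)
  prov$emscReference <- m
  prov$emscDegree <- degree
  provenance(out) <- prov
  list(spectra = out, fits = fit$fits[keep, , drop = FALSE])
}

#' Restrict a spectral set to wavenumber regions
#'
#' Retains exactly the points whose wavenumber lies in the union of the given
#' closed intervals; the axis remains descending.
#'
#' @param s a [SpectraSet-class].
#' @param regions list of inclusive `c(lo, hi)` (order-free) intervals.
#' @return the restricted [SpectraSet-class]; empty selection is an error.
#' @export
selectRegions <- function(s, regions = list(c(3200, 2800), c(1800, 600))) {
  wn <- wavenumbers(s)
  keep <- Reduce(`|`, lapply(regions, function(r) {
    r <- sort(as.numeric(r)); wn >= r[1L] & wn <= r[2L]
  }))
  .stopIf(!any(keep), "region selection retains no wavenumber points")
  res <- SpectraSet(absorbance(s)[, keep, drop = FALSE], wn[keep],
                    sampleMeta(s))
  metadata(res) <- metadata(s)
  res
}

#' Full preprocessing pipeline
#'
#' Applies, in order: Savitzky-Golay second derivative, wavenumber-region
#' selection, EMSC against the mean of the derivative-and-region-selected set
#' (or the frozen reference in `spec$reference`), then replicate averaging.
#' The spec and the EMSC reference actually used are recorded in the returned
#' set's provenance so that prediction-time data can be preprocessed
#' identically (pass `provenance(train)$spec` with its frozen reference, or
#' simply reuse the returned provenance via `applyProvenance()`).
#'
#' @param s a [SpectraSet-class] of replicate-level spectra.
#' @param spec a [preprocessSpec()].
#' @param average collapse replicates after correction (default TRUE).
#' @return the preprocessed [SpectraSet-class].
#' @export
preprocessPipeline <- function(s, spec = preprocessSpec(), average = TRUE) {
  d <- sgSecondDerivative(s, spec$sgWindow, spec$sgPolyorder)
  d <- selectRegions(d, spec$regions)
  em <- emscCorrect(d, reference = spec$reference, degree = spec$emscTerms)
  out <- em$spectra
  if (average) out <- averageReplicates(out)
  prov <- provenance(out)
  frozen <- spec
  frozen$reference <- prov$emscReference
  prov$spec <- frozen
  provenance(out) <- prov
  out
}

#' Preprocess new spectra with a stored provenance
#'
#' Runs [preprocessPipeline()] on `s` using the spec recorded in a previously
#' preprocessed set (including its frozen EMSC reference), so prediction-time
#' spectra are treated exactly like the training spectra.
#'
#' @param s a raw [SpectraSet-class].
#' @param prov a provenance list, e.g. `provenance(trainingSet)`.
#' @param average collapse replicates (default TRUE).
#' @return the preprocessed [SpectraSet-class].
#' @export
applyProvenance <- function(s, prov, average = TRUE) {
  .stopIf(is.null(prov$spec), "provenance carries no preprocessing spec")
  preprocessPipeline(s, prov$spec, average = average)
}
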