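mkSet <- function(x, wn) {
  if (is.null(dim(x))) x <- rbind(x)
  SpectraSet(x, wn, data.frame(sample_id = paste0("s", seq_len(nrow(x))),
                               cow_id = paste0("c", seq_len(nrow(x))),
                               dim = seq(5, length.out = nrow(x), by = 2),
                               parity = 1, replicate = 1))
}

test_that("SG second derivative is exact on polynomials", {
  wn <- seq(2000, 1000, by = -4)
  d <- sgSecondDerivative(mkSet(3 * wn^2 - 7 * wn + 2, wn))
  expect_equal(unname(absorbance(d)[1, ]), rep(6, length(wn) - 12),
               tolerance = 1e-9)
  dc <- sgSecondDerivative(mkSet(rep(4.2, length(wn)), wn))
  expect_equal(unname(absorbance(dc)[1, ]), rep(0, length(wn) - 12))
  # half-window dropped from each axis end
  expect_equal(wavenumbers(d), wn[7:(length(wn) - 6)])
})

test_that("SG output matches the per-window polynomial-fit oracle", {
  wn <- seq(4000, 3000, by = -3)
  y <- sin(wn / 40)
  got <- absorbance(sgSecondDerivative(mkSet(y, wn)))[1, ]
  expect_equal(unname(got), sgOracle(y, wn), tolerance = 1e-10)
})

test_that("SG interior agrees with signal::sgolayfilt", {
  wn <- seq(2000, 1600, by = -2)
  y <- withr::with_seed(3, cumsum(rnorm(length(wn))))
  got <- absorbance(sgSecondDerivative(mkSet(y, wn)))[1, ]
  ref <- signal::sgolayfilt(y, p = 2, n = 13, m = 2) / 2^2
  expect_equal(unname(got), ref[7:(length(y) - 6)], tolerance = 1e-8)
})

test_that("SG filter is linear and rejects bad axes", {
  wn <- seq(1900, 1700, by = -4)
  withr::with_seed(8, {
    x <- rnorm(length(wn)); y <- rnorm(length(wn))
    fx <- absorbance(sgSecondDerivative(mkSet(x, wn)))[1, ]
    fy <- absorbance(sgSecondDerivative(mkSet(y, wn)))[1, ]
    fxy <- absorbance(sgSecondDerivative(mkSet(2 * x - 3 * y, wn)))[1, ]
    expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)
  })
  expect_error(sgSecondDerivative(mkSet(rnorm(10), seq(100, 64, by = -4))),
               "shorter")
  badAxis <- sort(c(seq(1900, 1800, by = -4), 1857.3), decreasing = TRUE)
  expect_error(sgSecondDerivative(mkSet(rnorm(length(badAxis)), badAxis)),
               "uniform")
})

test_that("EMSC recovers an exact baseline model and is the identity on the reference", {
  wn <- seq(1900, 1500, by = -4)
  m <- exp(-((wn - 1740) / 30)^2)
  nu <- 2 * (wn - min(wn)) / diff(range(wn)) - 1
  z <- 2 * m + 0.5 + 0.1 * nu - 0.05 * nu^2
  em <- emscCorrect(mkSet(rbind(z, m), wn), reference = m)
  expect_equal(unlist(em$fits[1, c("a", "b", "d", "e")]),
               c(a = 0.5, b = 2, d = 0.1, e = -0.05), tolerance = 1e-8)
  expect_equal(unname(absorbance(em$spectra)[1, ]), m, tolerance = 1e-8)
  expect_equal(unlist(em$fits[2, c("a", "b", "d", "e")]),
               c(a = 0, b = 1, d = 0, e = 0), tolerance = 1e-8)
  expect_equal(unname(absorbance(em$spectra)[2, ]), m, tolerance = 1e-8)
})

test_that("EMSC agrees with an independent normal-equations solver on random spectra", {
  wn <- seq(1900, 1500, by = -4)
  m <- exp(-((wn - 1700) / 50)^2) + 0.3
  x <- withr::with_seed(13, {
    b <- runif(50, 0.5, 2)
    outer(b, m) + matrix(rnorm(50 * length(wn), sd = 0.1), 50)
  })
  em <- emscCorrect(mkSet(x, wn), reference = m)
  for (i in seq_len(50)) {
    o <- emscOracle(x[i, ], wn, m)
    expect_equal(unname(absorbance(em$spectra)[i, ]), o$corrected,
                 tolerance = 1e-8)
    expect_equal(unlist(em$fits[i, c("a", "b", "d", "e")]),
                 c(a = o$a, b = o$b, d = o$d, e = o$e), tolerance = 1e-8)
  }
})

test_that("EMSC is scale-equivariant and excludes near-orthogonal spectra", {
  wn <- seq(1900, 1500, by = -4)
  m <- exp(-((wn - 1700) / 50)^2) + 0.2
  z <- 1.4 * m + 0.1
  for (cc in c(0.1, 3, 10)) {
    em <- emscCorrect(mkSet(rbind(z, cc * z), wn), reference = m)
    expect_equal(em$fits$b[2], cc * em$fits$b[1], tolerance = 1e-10)
    expect_equal(absorbance(em$spectra)[2, ], absorbance(em$spectra)[1, ],
                 tolerance = 1e-10)
  }
  nu <- 2 * (wn - min(wn)) / diff(range(wn)) - 1
  flat <- 0.2 + 0.05 * nu            # pure baseline, no reference component
  expect_warning(em2 <- emscCorrect(mkSet(rbind(z, flat), wn), reference = m),
                 "near-orthogonal")
  expect_equal(nSamples(em2$spectra), 1L)
})

test_that("region selection matches a brute-force membership test", {
  s <- toySet(2, wn = seq(3500, 500, by = -7))
  r <- selectRegions(s)
  expect_false(any(abs(wavenumbers(r) - 2500) < 1))
  expect_true(any(abs(wavenumbers(r) - 1000) < 4))
  keep <- (wavenumbers(s) >= 2800 & wavenumbers(s) <= 3200) |
    (wavenumbers(s) >= 600 & wavenumbers(s) <= 1800)
  expect_equal(wavenumbers(r), wavenumbers(s)[keep])
  # full-range selection is the identity
  full <- selectRegions(s, list(range(wavenumbers(s))))
  expect_equal(absorbance(full), absorbance(s))
  expect_error(selectRegions(s, list(c(4500, 4600))), "no wavenumber")
  # random intervals vs brute force
  withr::with_seed(17, for (i in 1:10) {
    iv <- sort(runif(2, 500, 3500))
    keep2 <- wavenumbers(s) >= iv[1] & wavenumbers(s) <= iv[2]
    if (!any(keep2)) next
    expect_equal(wavenumbers(selectRegions(s, list(iv))),
                 wavenumbers(s)[keep2])
  })
})

test_that("region selection and EMSC commute when the reference is region-recomputed", {
  s <- smallCohortConfig(seed = 2)
  sim <- simulateCohort(s)
  d <- sgSecondDerivative(sim$spectra)
  a <- emscCorrect(selectRegions(d), reference = "mean")$spectra
  bFull <- emscCorrect(d, reference = "mean")$spectra
  # correcting after selection equals selecting after correcting *with the
  # reference recomputed on the selected region*
  bSel <- selectRegions(d)
  b <- emscCorrect(bSel, reference = colMeans(absorbance(bSel)))$spectra
  expect_equal(absorbance(a), absorbance(b), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(absorbance(a),
                                absorbance(selectRegions(bFull)))))
})

test_that("pipeline collapses exact-copy triplicates to the single-replicate result", {
  wn <- seq(4000, 500, by = -12)
  base <- syntheticSpectrum(c(fat = 4, protein = 3.4, lactose = 4.9,
                              unsat = 25, chain = 32), wn)[1, ]
  x3 <- rbind(base, base, base) * c(1, 1, 1) + 0.01
  meta3 <- data.frame(sample_id = paste0("s", 1:3), cow_id = "c1", dim = 5,
                      parity = 1, replicate = 1:3)
  meta1 <- meta3[1, ]
  p3 <- preprocessPipeline(SpectraSet(x3, wn, meta3))
  p1 <- preprocessPipeline(SpectraSet(rbind(base + 0.01), wn, meta1))
  expect_equal(unname(absorbance(p3)), unname(absorbance(p1)),
               tolerance = 1e-10)
})

test_that("pipeline output axis lies inside the modelling regions and provenance is reusable", {
  sim <- simulateCohort(smallCohortConfig(seed = 4))
  pp <- preprocessPipeline(sim$spectra)
  wn <- wavenumbers(pp)
  expect_true(all((wn >= 2800 & wn <= 3200) | (wn >= 600 & wn <= 1800)))
  prov <- provenance(pp)
  expect_s3_class(prov$spec, "PreprocessSpec")
  expect_true(is.numeric(prov$spec$reference))
  # idempotency: re-correcting already-corrected data against the frozen
  # reference changes nothing (derivative step skipped on the second pass)
  em2 <- emscCorrect(pp, reference = prov$emscReference)
  keep <- match(sampleMeta(em2$spectra)$sample_id, sampleMeta(pp)$sample_id)
  expect_equal(absorbance(em2$spectra), absorbance(pp)[keep, , drop = FALSE],
               tolerance = 1e-6)
  # prediction-time data preprocessed identically via stored provenance
  newPP <- applyProvenance(sim$spectra, prov)
  expect_equal(absorbance(newPP), absorbance(pp), tolerance = 1e-10)
})

test_that("EMSC moves corrected group means toward the noiseless derivative", {
  cfg <- smallCohortConfig(seed = 12)
  sim <- simulateCohort(cfg)
  clean <- simulateCohort(smallCohortConfig(seed = 12, noiseSd = 0,
                                            bRange = c(1, 1), aRange = c(0, 0),
                                            dRange = c(0, 0), eRange = c(0, 0)))
  dClean <- selectRegions(sgSecondDerivative(averageReplicates(clean$spectra)))
  dirty <- selectRegions(sgSecondDerivative(sim$spectra))
  ref <- colMeans(absorbance(dirty))
  corr <- emscCorrect(dirty, reference = ref)$spectra
  # the noiseless derivative expressed on the same corrected scale
  target <- absorbance(emscCorrect(dClean, reference = ref)$spectra)
  gm <- function(s) {
    a <- averageReplicates(s)
    a[, match(sampleMeta(dClean)$sample_id, sampleMeta(a)$sample_id)]
  }
  l2 <- function(s) rowSums((absorbance(gm(s)) - target)^2)
  better <- mean(l2(corr) < l2(dirty))
  expect_gte(better, 0.95)
})
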