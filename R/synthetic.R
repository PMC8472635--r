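#' Default spectral band table
#'
#' Gaussian band parameters linking the five generator components (fat,
#' protein, lactose, an unsaturation index and a chain-length index) to the
#' mid-infrared absorbance spectrum. The named milk bands (ester carbonyl
#' ~1748 cm^-1, amide I/II at 1657/1549 cm^-1, lactose C-O at 1074 cm^-1) are
#' complemented by CH-stretch bands (2920/2850 cm^-1, fat and chain length)
#' and an olefinic =C-H band (~3008 cm^-1, unsaturation) so that fatty-acid
#' information is encoded in the 3200-2800 cm^-1 region; those centres come
#' from general mid-IR band assignments and are fully configurable.
#'
#' @return data.frame with columns `component`, `center` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1), `amplitude` (absorbance per unit concentration).
#' @export
bandTable <- function() {
  data.frame(
    component = c("fat", "fat", "fat", "fat",
                  "protein", "protein", "protein",
                  "lactose", "lactose",
                  "unsat", "chain", "chain"),
    center = c(2920, 2850, 1748, 1160,
               1657, 1549, 1240,
               1074, 1042,
               3008, 2922, 2853),
    width = c(14, 12, 12, 16,
              20, 18, 20,
              22, 18,
              9, 13, 11),
    amplitude = c(0.010, 0.007, 0.050, 0.015,
                  0.055, 0.045, 0.008,
                  0.045, 0.030,
                  0.0040, 0.0030, 0.0022))
}

#' Fatty-acid feature parameters of the generator
#'
#' Each feature is `mean + slope * m + residual`, where `m` is a standardised
#' latent energy-balance/mobilisation factor (high in early lactation, raised
#' further in ketotic cows) and the residual is independent noise. `dir` gives
#' the sign of the slope; `residFrac` the fraction of the feature's SD that is
#' residual (so `slope = dir * sd * sqrt(1 - residFrac^2)`). CLA and PUFA are
#' almost entirely residual, so they carry little recoverable spectral signal.
#' SAT is obtained by closure (`94.7 - MUFA - PUFA`) and is not listed.
#'
#' @return data.frame with columns `feature`, `mean`, `sd`, `dir`, `residFrac`.
#' @export
faParamTable <- function() {
  data.frame(
    feature = c("C10:0", "C14:0", "C16:0", "C18:0", "C18:1cis9",
                "CLA", "MUFA", "PUFA"),
    mean = c(3.1, 11.1, 27.9, 11.5, 20.3, 0.5, 24.9, 2.3),
    sd = c(0.7, 1.6, 3.1, 1.9, 3.6, 0.1, 3.9, 0.3),
    dir = c(-1, -1, -1, 1, 1, 1, 1, 1),
    residFrac = c(0.15, 0.15, 0.15, 0.15, 0.15, 0.95, 0.15, 0.95))
}

#' Thrice-weekly sampling schedule over the study window
#' @param low,high inclusive DIM bounds (defaults 5 and 100).
#' @return integer vector of sampling days (three per week).
#' @export
defaultSchedule <- function(low = 5L, high = 100L) {
  d <- seq.int(low, high)
  d[(d - low) %% 7L %in% c(0L, 2L, 4L)]
}

#' Cohort generator configuration
#'
#' Defaults emulate the study design: 61 cows sampled thrice weekly over DIM
#' 5-100 in triplicate on a 4000-500 cm^-1 axis with 3 cm^-1 point spacing
#' (a 6 cm^-1-resolution interferogram is commonly stored at about half that
#' spacing), parity mix matching the reported per-parity sample shares, a
#' 21/61 subclinical-ketosis prevalence, fatty-acid levels and spreads
#' matching the reported summary table, and gross-composition lactation
#' curves with the reported means.
#'
#' @param nCows number of cows.
#' @param dims sampling days (default [defaultSchedule()]).
#' @param replicates spectra per milk sample (default 3).
#' @param parityDistribution probabilities over parities 1-6 (must sum to 1).
#' @param ketosisPrevalence expected fraction of ketotic cows.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param grid named vector `c(start, stop, step)` of the wavenumber axis in
#'   cm^-1.
#' @param bands band table, see [bandTable()].
#' @param faParams fatty-acid parameters, see [faParamTable()].
#' @param noiseSd white-noise SD per replicate spectrum (absorbance units).
#' @param bRange,aRange,dRange,eRange per-replicate baseline parameter ranges
#'   (multiplicative, additive, linear, quadratic); collapse them (and set
#'   `noiseSd = 0`) for the noiseless limit.
#' @param trendAmplitude,trendDecay latent-factor lactation trend
#'   `trendAmplitude * exp(-(dim-5)/trendDecay)`; the factor is standardised
#'   over the realised cohort, so only the trend *shape* and the noise ratios
#'   matter (feature means and SDs then land on the configured values by
#'   construction).
#' @param cowSd,sampleSd cow-level random effect and day-to-day SD of the
#'   latent factor (pre-standardisation units, i.e. relative to
#'   `trendAmplitude`).
#' @param ketoOffset,ketoDecay early-lactation latent-factor offset in ketotic
#'   cows and its e-folding decay in days (offset has decayed to ~2% of its
#'   initial value by DIM 100); magnitudes are order-of-magnitude choices.
#' @param parityFatEffect added milk-fat percent per parity step (capped at
#'   parity 4, "adult" cows).
#' @param gross overrides for the gross-composition curve parameters (see the
#'   vignette for the parameterisation).
#' @return a list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(nCows = 61L, dims = defaultSchedule(),
                         replicates = 3L,
                         parityDistribution = c(895, 608, 343, 326, 81, 76) / 2329,
                         ketosisPrevalence = 21 / 61,
                         seed = 1L,
                         grid = c(start = 4000, stop = 500, step = 3),
                         bands = bandTable(), faParams = faParamTable(),
                         noiseSd = 0.002,
                         bRange = c(0.95, 1.10), aRange = c(-0.02, 0.02),
                         dRange = c(-0.01, 0.01), eRange = c(-0.01, 0.01),
                         trendAmplitude = 2.4, trendDecay = 60,
                         cowSd = 0.4, sampleSd = 0.45,
                         ketoOffset = 0.8, ketoDecay = 25,
                         parityFatEffect = 0.12, gross = list()) {
  .stopIf(abs(sum(parityDistribution) - 1) > 1e-8,
          "parity probabilities must sum to 1")
  .stopIf(any(c(noiseSd, cowSd, sampleSd) < 0), "SDs must be nonnegative")
  .stopIf(grid[["step"]] <= 0, "grid step must be positive")
  .stopIf(ketosisPrevalence < 0 || ketosisPrevalence > 1,
          "prevalence must be in [0,1]")
  g <- utils::modifyList(list(
    fatScale = 6.00, fatPowB = -0.18, fatExpC = -0.004,
    fatCowSd = 0.6, fatNoiseSd = 0.45,
    proteinBase = 3.30, proteinEarly = 0.90, proteinDecay = 14,
    proteinCowSd = 0.15, proteinNoiseSd = 0.10,
    lactoseBase = 4.78, lactosePeak = 0.28, lactosePeakDay = 35,
    lactoseCowSd = 0.13, lactoseNoiseSd = 0.08), gross)
  structure(list(nCows = as.integer(nCows), dims = as.integer(dims),
                 replicates = as.integer(replicates),
                 parityDistribution = parityDistribution,
                 ketosisPrevalence = ketosisPrevalence, seed = seed,
                 grid = grid, bands = bands, faParams = faParams,
                 noiseSd = noiseSd, bRange = bRange, aRange = aRange,
                 dRange = dRange, eRange = eRange,
                 trendAmplitude = trendAmplitude, trendDecay = trendDecay,
                 cowSd = cowSd, sampleSd = sampleSd,
                 ketoOffset = ketoOffset, ketoDecay = ketoDecay,
                 parityFatEffect = parityFatEffect, gross = g),
            class = "CohortConfig")
}

#' Clean spectrum from component concentrations
#'
#' Evaluates the Gaussian band mixture `sum_b amplitude_b * conc\[component_b\]
#' * exp(-(nu - center_b)^2 / (2 width_b^2))` on the given axis. The spectrum
#' is linear in each component's concentration by construction.
#'
#' @param concentrations numeric matrix (samples by components) or vector,
#'   with (column) names matching `bands$component`.
#' @param wavenumbers numeric axis in cm^-1.
#' @param bands band table, see [bandTable()].
#' @return matrix of clean spectra, samples by wavenumbers.
#' @export
syntheticSpectrum <- function(concentrations, wavenumbers,
                              bands = bandTable()) {
  if (is.null(dim(concentrations)))
    concentrations <- matrix(concentrations, 1L,
                             dimnames = list(NULL, names(concentrations)))
  comp <- sort(unique(bands$component))
  miss <- setdiff(comp, colnames(concentrations))
  .stopIf(length(miss) > 0, "no concentration for component(s): %s",
          paste(miss, collapse = ", "))
  .stopIf(any(bands$width <= 0), "band widths must be positive")
  B <- matrix(0, length(comp), length(wavenumbers),
              dimnames = list(comp, NULL))
  for (i in seq_len(nrow(bands)))
    B[bands$component[i], ] <- B[bands$component[i], ] +
      bands$amplitude[i] *
      exp(-(wavenumbers - bands$center[i])^2 / (2 * bands$width[i]^2))
  concentrations[, comp, drop = FALSE] %*% B
}

#' Apply a multiplicative/polynomial baseline to spectra
#'
#' Returns `b*x + a + d*nu + e*nu^2` with `nu` the axis affinely mapped to
#' \[-1, 1\] — the algebraic inverse of the EMSC model fitted by
#' [emscCorrect()] when the same reference is used.
#'
#' @param x spectrum vector or samples-by-wavenumbers matrix.
#' @param wavenumbers the axis.
#' @param a,b,d,e additive, multiplicative, linear and quadratic terms
#'   (scalars or per-sample vectors); `b = 0` is an error.
#' @return transformed spectra, same shape as `x`.
#' @export
applyBaseline <- function(x, wavenumbers, a = 0, b = 1, d = 0, e = 0) {
  .stopIf(any(b == 0), "degenerate multiplicative term b = 0")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1L)
  rng <- range(wavenumbers)
  nu <- if (diff(rng) > 0) 2 * (wavenumbers - rng[1L]) / diff(rng) - 1
        else rep(0, length(wavenumbers))
  out <- b * x + a + outer(rep(1, nrow(x)) * d, nu) +
    outer(rep(1, nrow(x)) * e, nu^2)
  if (vec) out[1L, ] else out
}

#' Assign blood BHB concentrations to cows
#'
#' Draws BHB from a two-component lognormal mixture: a Bernoulli(prevalence)
#' draw selects the component, then BHB comes from a lognormal centred below
#' 1 ng/mL (normal cows) or above it (ketotic cows), each truncated to its
#' side of the 1.0 threshold so the expected ketotic fraction equals the
#' prevalence exactly. Ketosis flag and tier are derived via [cowRecords()].
#'
#' @param cows data.frame with at least `cow_id` and `parity`.
#' @param prevalence expected ketotic fraction in \[0, 1\].
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return the cow table with `bhb_ng_per_ml`, `ketosis`, `tier` columns.
#' @export
assignBHB <- function(cows, prevalence = 21 / 61, seed = NULL) {
  .stopIf(prevalence < 0 || prevalence > 1, "prevalence must be in [0,1]")
  n <- nrow(cows)
  .withSeed(seed, {
    keto <- stats::runif(n) < prevalence
    mlN <- log(0.55); slN <- 0.28      # normal component, centred ~0.55
    mlK <- log(1.50); slK <- 0.42      # ketotic component, centred ~1.5
    bhb <- numeric(n)
    if (any(!keto)) {
      hi <- stats::plnorm(1, mlN, slN)
      bhb[!keto] <- stats::qlnorm(stats::runif(sum(!keto), 0, hi), mlN, slN)
    }
    if (any(keto)) {
      lo <- stats::plnorm(1, mlK, slK)
      bhb[keto] <- stats::qlnorm(stats::runif(sum(keto), lo, 1), mlK, slK)
    }
    cows$bhb_ng_per_ml <- bhb
    cowRecords(cows)
  })
}

#' Simulate a milk FTIR cohort
#'
#' Generates a cohort of cow-level dry-film FTIR replicate spectra with
#' metadata, blood BHB, and per-sample ground truth. Each clean spectrum is
#' the Gaussian band mixture of [syntheticSpectrum()] evaluated at the
#' sample's true gross composition and fatty-acid-derived indices
#' (unsaturation = MUFA, chain length = C18:0 + C18:1cis9); each replicate is
#' then transformed by a random multiplicative/polynomial baseline
#' ([applyBaseline()]) plus white noise. Fatty-acid trajectories follow a
#' single latent mobilisation factor: C18:0, C18:1cis9 and MUFA decrease with
#' DIM while C10:0, C14:0, C16:0 and SAT increase, and ketotic cows get an
#' early-lactation offset (C14:0 down, C18:1cis9 up) decaying to ~0 by DIM
#' 100. Deterministic given `cfg$seed`.
#'
#' @param cfg a [cohortConfig()].
#' @return `list(spectra = replicate-level SpectraSet, cows = cow record
#'   data.frame, truth = per-(cow, dim) ground-truth data.frame whose
#'   sample_id matches the replicate-averaged ids)`.
#' @export
simulateCohort <- function(cfg = cohortConfig()) {
  .stopIf(!inherits(cfg, "CohortConfig"), "cfg must come from cohortConfig()")
  .stopIf(length(cfg$dims) < 2L,
          "sampling schedule yields %d sample(s) per cow; need >= 2",
          length(cfg$dims))
  .withSeed(cfg$seed, {
    wn <- seq(cfg$grid[["start"]], cfg$grid[["stop"]], by = -cfg$grid[["step"]])
    nC <- cfg$nCows
    cows <- data.frame(
      cow_id = sprintf("cow%03d", seq_len(nC)),
      parity = sample(1:6, nC, replace = TRUE, prob = cfg$parityDistribution))
    cows <- assignBHB(cows, cfg$ketosisPrevalence, seed = NULL)

    dims <- cfg$dims
    nD <- length(dims)
    ci <- rep(seq_len(nC), each = nD)          # cow index per sample
    dim_ <- rep(dims, nC)
    nS <- nC * nD

    # latent mobilisation factor m, standardised over the realised cohort so
    # that feature means/SDs land on the configured values by construction
    trend <- cfg$trendAmplitude * exp(-(dim_ - 5) / cfg$trendDecay)
    ketoTerm <- cfg$ketoOffset * exp(-(dim_ - 5) / cfg$ketoDecay) *
      cows$ketosis[ci]
    cowRE <- stats::rnorm(nC, 0, cfg$cowSd)
    m <- trend + ketoTerm + cowRE[ci] + stats::rnorm(nS, 0, cfg$sampleSd)
    mSd <- stats::sd(m)
    m <- if (is.finite(mSd) && mSd > 1e-12) (m - mean(m)) / mSd else m - mean(m)

    fp <- cfg$faParams
    slope <- fp$dir * fp$sd * sqrt(1 - fp$residFrac^2)
    FA <- matrix(0, nS, nrow(fp), dimnames = list(NULL, fp$feature))
    for (i in seq_len(nrow(fp)))
      FA[, i] <- fp$mean[i] + slope[i] * m +
        stats::rnorm(nS, 0, fp$residFrac[i] * fp$sd[i])
    SAT <- 94.7 - FA[, "MUFA"] - FA[, "PUFA"]
    FA <- pmax(cbind(FA, SAT = SAT), 0.01)
    colnames(FA)[ncol(FA)] <- "SAT"

    g <- cfg$gross
    fat <- g$fatScale * dim_^g$fatPowB * exp(-g$fatExpC * dim_) +
      cfg$parityFatEffect * (pmin(cows$parity[ci], 4L) - 1L) +
      stats::rnorm(nC, 0, g$fatCowSd)[ci] + stats::rnorm(nS, 0, g$fatNoiseSd)
    fat <- pmax(fat, 0.5)
    protein <- g$proteinBase + g$proteinEarly * exp(-dim_ / g$proteinDecay) +
      stats::rnorm(nC, 0, g$proteinCowSd)[ci] +
      stats::rnorm(nS, 0, g$proteinNoiseSd)
    lactose <- g$lactoseBase +
      g$lactosePeak * (dim_ / g$lactosePeakDay) *
        exp(1 - dim_ / g$lactosePeakDay) +
      stats::rnorm(nC, 0, g$lactoseCowSd)[ci] +
      stats::rnorm(nS, 0, g$lactoseNoiseSd)

    conc <- cbind(fat = fat, protein = protein, lactose = lactose,
                  unsat = FA[, "MUFA"],
                  chain = FA[, "C18:0"] + FA[, "C18:1cis9"])
    clean <- syntheticSpectrum(conc, wn, cfg$bands)

    nR <- cfg$replicates
    rep_ <- rep(seq_len(nR), times = nS)
    si <- rep(seq_len(nS), each = nR)          # sample index per replicate
    nRep <- nS * nR
    a <- stats::runif(nRep, cfg$aRange[1L], cfg$aRange[2L])
    b <- stats::runif(nRep, cfg$bRange[1L], cfg$bRange[2L])
    d <- stats::runif(nRep, cfg$dRange[1L], cfg$dRange[2L])
    e <- stats::runif(nRep, cfg$eRange[1L], cfg$eRange[2L])
    x <- applyBaseline(clean[si, , drop = FALSE], wn, a = a, b = b,
                       d = d, e = e)
    if (cfg$noiseSd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, cfg$noiseSd), nrow(x))

    meta <- data.frame(
      sample_id = sprintf("%s_d%03d_r%d", cows$cow_id[ci[si]], dim_[si], rep_),
      cow_id = cows$cow_id[ci[si]], dim = dim_[si],
      parity = cows$parity[ci[si]], replicate = rep_)
    truth <- data.frame(
      sample_id = sprintf("%s_d%03d", cows$cow_id[ci], dim_),
      cow_id = cows$cow_id[ci], dim = dim_,
      fat = fat, protein = protein, lactose = lactose,
      FA, check.names = FALSE)
    list(spectra = SpectraSet(x, wn, meta), cows = cows, truth = truth)
  })
}

#' Write a simulated cohort to CSV files
#'
#' Writes the spectra/metadata pair, the cow table, the ground-truth table,
#' and a JSON sidecar recording the configuration and seed.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param cfg the [cohortConfig()] used (stored in the sidecar).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(sim, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSpectra(sim$spectra, file.path(dir, "spectra.csv"),
               file.path(dir, "metadata.csv"))
  data.table::fwrite(sim$cows, file.path(dir, "cows.csv"))
  data.table::fwrite(sim$truth, file.path(dir, "ground_truth.csv"))
  if (!is.null(cfg)) {
    side <- cfg
    side$bands <- NULL; side$faParams <- NULL
    jsonlite::write_json(side, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}
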