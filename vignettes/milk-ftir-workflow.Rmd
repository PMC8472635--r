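---
title: "Dry-film FTIR milk analysis across lactation: methods and design"
author: "milkFTIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dry-film FTIR milk analysis across lactation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkFTIR)
```

## The problem

Milk composition drifts systematically through early lactation. In the first
weeks after calving a dairy cow's energy demand exceeds her intake (negative
energy balance); she mobilises adipose tissue, which raises long-chain fatty
acids (C18:0, C18:1cis9, MUFA as a group) in the milk, while de novo synthesis
of short- and medium-chain acids (C10:0, C14:0, C16:0, the saturated sum)
recovers only as energy balance improves. Cows whose energy deficit tips into
subclinical ketosis — diagnosed here by blood β-hydroxybutyrate (BHB) above
1.0 ng/mL — show an exaggerated version of this pattern early in lactation:
less C14:0, more C18:1cis9, converging back to the normal-cow trajectory by
around 100 days in milk (DIM).

Dry-film FTIR spectroscopy (a milk droplet dried on a silicon plate, measured
in transmission) gives a water-free mid-infrared fingerprint from which both
gross composition and fatty-acid features can be read. This package
implements a complete, testable analysis chain for such data: spectral
preprocessing, PLSR calibration of nine fatty-acid features, PCA exploration
of DIM and parity structure, sparsity-optimised PLS-DA classification of
lactation stage under leave-one-cow-out validation, and the BHB-threshold
ketosis comparison — plus a synthetic-cohort generator so that every stage is
exercised end to end with no instrument data.

## Data model

A `SpectraSet` holds an absorbance matrix on a strictly descending wavenumber
axis with per-sample metadata (`cow_id`, `dim`, `parity`, `replicate`, and
derived `stage`/`parity_group` labels). It extends `SummarizedExperiment`, so
subsetting, `colData` and `metadata` behave as Bioconductor users expect.
Lactation stage is DIM1 for 5 ≤ DIM ≤ 50 and DIM2 for 50 < DIM ≤ 100;
parities collapse to PAR1, PAR2 and PAR>2 (older cows are essentially
"adult"). Cow records carry blood BHB: a cow is ketotic iff BHB > 1.0 ng/mL
(strict; exactly 1.0 is normal), with tiers normal ≤ 1.0 < mid ≤ 2.0 < high.
The upper tier boundary is placed at (2.0, ∞) for consistency with the strict
primary threshold; the exact-2.0 case is arbitrary and documented here. BHB
units are carried verbatim as ng/mL without conversion.

## Preprocessing

The chain is: quality check → Savitzky–Golay second derivative → region
selection → EMSC → replicate averaging. Preprocessing runs on replicate-level
spectra and the replicate mean is taken *after* correction.

* **Quality check.** Flags spectra with any non-finite value, or whose
  Pearson correlation to the median spectrum falls below
  `median(r) − z·mad(r)` (default z = 3.5). This is a deliberate,
  reproducible stand-in for an instrument-side "standard quality check";
  it is distribution-free and configurable, not a reconstruction of any
  particular vendor rule.
* **Savitzky–Golay second derivative** with a 13-point window and a degree-2
  polynomial. The filter is the exact local least-squares solution, so it is
  exact on quadratics; output is scaled by the squared point spacing to
  absorbance/(cm⁻¹)². The half-window (6 points) at each axis end is dropped
  rather than extrapolated — polynomial extrapolation would fabricate
  curvature at the spectrum ends.
* **Region selection** keeps 3200–2800 cm⁻¹ (CH-stretch, fatty-acid
  information) and 1800–600 cm⁻¹ (carbonyl/amide/fingerprint), closed
  intervals.
* **EMSC** fits each spectrum as `a + b·m + d·ν̃ + e·ν̃²` against the mean
  spectrum `m` of the derivative-and-region-selected set (ν̃ is the axis
  mapped affinely to [−1, 1]) and returns `(z − a − d·ν̃ − e·ν̃²)/b`. Plain
  least squares; the baseline polynomials are *not* orthogonalised against
  the reference (variants differ — this one is stated so results are
  reproducible). The reference is frozen into the returned provenance, and
  `applyProvenance()` preprocesses prediction-time spectra identically.
  Spectra nearly orthogonal to the reference (|b| < 1e−8) are excluded with
  a warning rather than silently inverted.

Two ordering choices were genuinely open and are fixed here: the quality
check runs before the derivative (a gross outlier should not influence the
EMSC reference), and EMSC runs on the concatenated modelling regions rather
than the full axis (the normalisation then lives in the same space as the
models that consume it).

## Factor models

PCA is column-centred SVD with a deterministic sign convention (each
loading's largest-magnitude element is positive); explained fractions are
squared singular values over their total. PLS regression is single-response
NIPALS, computed through its Gram-matrix kernel form (only `X'X` and `X'y`
are deflated), which makes grouped cross-validation over a parameter grid
cheap: per fold the full-data crossproduct is downdated by the held-out
cow's rows instead of refitting from scratch. The kernel recursion is
verified in the tests against a naive X-deflation NIPALS and, at full rank,
against ordinary least squares.

The number of latent variables is chosen by cross-validated RMSECV with a 2%
parsimony band: the smallest count whose RMSECV is within 2% of the curve
minimum. The proprietary "default criteria" of commercial chemometrics
software are not public; a global-minimum rule with a parsimony band is the
standard reproducible alternative, and the single constant is exposed.
Calibration supports two regimes: *pooled* (all 244 calibration samples,
random 10% segments) and *test-set* (219-sample external set for training,
25 held-out study samples for RMSEP/R²). R² is computed against the
test-set mean — conventions differ, so this is stated. Nine independent
PLS1 models are fitted (one per feature) rather than one multi-response
model, matching per-feature calibration practice.

## Sparse PLS-DA

Lactation-stage classification (DIM1 vs DIM2) uses PLS1-DA on a 0/1 dummy
with per-LV hard thresholding: the dense weight vector is truncated to its
top `⌈(1−s)·p⌉` entries by absolute value (floor of one variable) and
renormalised, making the per-LV cardinality exact — this matches the
"fraction of variables removed" framing of the sparsity parameter; soft
thresholding variants exist but do not give exact counts. Sparsity
(0.90–0.99) and LV count (1–10) are optimised by leave-one-cow-out CV on
plain accuracy (balanced accuracy is selectable); ties break toward fewer
LVs, then higher sparsity, favouring interpretability. The decision rule
thresholds the predicted dummy at 0.5 — simpler than LDA on scores and
adequate for two roughly balanced classes. Four models are fitted: all
samples, PAR1, PAR2, PAR>2. Correlation loadings (Pearson correlations of
spectral variables, predicted fatty acids, and 0/1 design indicators with
the first two LV score vectors) summarise each model; since score vectors
are mutually uncorrelated, every point lies inside the unit circle.

## The synthetic cohort

The generator emulates the study design end to end: 61 cows sampled thrice
weekly over DIM 5–100 in triplicate; a 4000–500 cm⁻¹ axis at 3 cm⁻¹ point
spacing (an instrument reporting 6 cm⁻¹ resolution commonly stores about
half that spacing; both are configurable); parity mix matching the
per-parity sample shares of such cohorts; and a 21/61 ketosis prevalence.

Each clean spectrum is a Gaussian band mixture over five components: fat
(ester carbonyl 1748 cm⁻¹, CH₂ stretches 2920/2850 cm⁻¹, ester C–O
1160 cm⁻¹), protein (amide I/II 1657/1549 cm⁻¹), lactose (C–O 1074 and
1042 cm⁻¹), an unsaturation index (olefinic 3008 cm⁻¹) defined as the true
MUFA value, and a chain-length index (CH₂ 2922/2853 cm⁻¹) defined as
C18:0 + C18:1cis9. The CH-region centres come from general mid-IR band
assignments, not from any specific dataset, and are config-exposed. Each
replicate is then distorted by `b·x + a + d·ν̃ + e·ν̃²` with per-replicate
uniform draws (b ∈ [0.95, 1.10], a ∈ ±0.02, d, e ∈ ±0.01) plus white noise
(SD 0.002 absorbance) — the exact algebraic inverse of the EMSC model, so
correction quality is checkable to machine precision.

Fatty-acid features follow a single latent mobilisation factor *m*: high in
early lactation (exponential decay with a 60-day constant), raised further
in ketotic cows by an early offset decaying with a 25-day constant (≈2% left
by DIM 100), with cow-level (SD 0.4) and day-to-day (SD 0.45) noise. The
factor is standardised over the realised cohort, so each feature
`mean + slope·m + residual` lands exactly on its configured mean and SD
(defaults: the reported cohort table — e.g. C16:0 27.9 ± 3.1, C18:1cis9
20.3 ± 3.6). Slopes are negative for C10:0/C14:0/C16:0 and positive for
C18:0/C18:1cis9/MUFA, reproducing the reported trend directions; SAT is
obtained by closure (94.7 − MUFA − PUFA, the reported mean sum), which keeps
SAT + MUFA + PUFA physical and gives SAT the mirrored trend automatically.
Per-feature residuals are 15% of the SD — except CLA and PUFA at 95%, which
deliberately makes them nearly unpredictable from the spectra, mirroring the
observation that those two calibrations perform poorly. Because the
unsaturation and chain-length indices are linear maps of the same features
the models must recover, PLSR recoverability is guaranteed *by
construction*: a failed recovery test indicts the modelling code, not the
generator. Gross composition uses a Wood-type curve for fat (`a·t^b·e^{−ct}`
with b < 0, c < 0: high at calving, minimum near DIM 45, mild rise to DIM
100), a declining exponential to a plateau for protein, and a broad
mid-lactation bump peaking near DIM 35 for lactose; parity adds fat
(+0.12%/parity, capped at parity 4). Day-to-day noise magnitudes were set so
an individual cow's C16:0 trace scatters by roughly ±2 percentage points,
the scale of published individual-cow trajectories.

BHB is drawn from a two-component lognormal mixture — a Bernoulli
(prevalence) pick of component, then a lognormal centred at 0.55 ng/mL
truncated to (0, 1] for normal cows or centred at 1.5 ng/mL truncated to
(1, ∞) for ketotic cows — so the expected ketotic fraction equals the
prevalence exactly and the mid/high tier split lands near the reported
15:6. Ketosis effect magnitudes on the fatty acids are order-of-magnitude
choices (no numeric values are published for them) and are config-exposed.

**What the generator does not emulate:** water-vapour/CO₂ artefacts,
scatter beyond the polynomial baseline, instrument drift between sessions,
more than one latent biological axis behind the fatty-acid covariance, and
missing/irregular sampling. Passing tests therefore demonstrate that the
*pipeline* recovers planted structure under its own assumptions; they are
not evidence about any particular real dataset.

## Problem sizes and numerical choices

The package's own study scale is 61 cows × 41 sampling days × 3 replicates
(≈7,500 replicate spectra, 534 retained wavenumber points); the full
orchestrated run (`runStudy()`) completes in about a minute on one CPU.
Unit and property tests use reduced cohorts (8–24 cows, coarser 12 cm⁻¹
grids) because the properties they check are scale-free; the
parameter-recovery and null-control checks run at the full 61-cow scale.
Determinism is verified by re-running the whole study at a reduced scale
and comparing output files byte by byte — determinism does not depend on
scale.

Numerical tie-breaks and degenerate cases: sparsity counts use
`⌈(1−s)p⌉` with a 1e−9 guard against floating-point fuzz and a floor of one
retained variable; EMSC refuses singular designs and excludes |b| < 1e−8
spectra; PCA errors on zero-variance input; CV folds whose training data
contain a single class are skipped with a warning; an empty DIM filter
result warns rather than errors; zero-variance variables get (0, 0)
correlation loadings with a flag. Bootstrap CIs for the ketosis contrasts
are percentile intervals over 1000 seeded cow-level resamples — the
comparison is descriptive in origin, so the interval is an extension, not a
reconstruction, and with ~20 cows per group percentile intervals run
slightly narrow of nominal.

## Known limitations

* The quality-check criterion and the LV-selection rule are reproducible
  stand-ins for unspecified or proprietary procedures.
* The single-latent-factor fatty-acid model understates the dimensionality
  of real milk FA covariance; classification and recovery results on
  synthetic data are accordingly optimistic in some respects (one clean
  axis) and pessimistic in others (no auxiliary discriminative chemistry).
* Stage classification near the DIM-50 boundary is intrinsically ambiguous
  at realistic day-to-day variation; even an oracle given the noiseless
  composition misclassifies a substantial share of boundary samples.
* No proprietary instrument formats, no atmospheric compensation, no
  multiclass classification, no energy-balance prediction.

## A minimal run

```{r, eval = FALSE}
cfg <- runConfig(seed = 1, outDir = "milkftir_out")
res <- runStudy(cfg)
res$dim$scores          # PC scores of per-DIM average spectra vs DIM
res$calibration$pooled  # nine PLSR models with RMSECV
res$classModels$all     # sparse PLS-DA model + correlation loadings
res$ketosis$contrasts   # early-window ketotic-vs-normal FA contrasts
```
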