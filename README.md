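# milkFTIR

Chemometric analysis of dry-film FTIR milk spectra across early lactation.

## What this is for

Milk composition changes systematically over the first 100 days in milk
(DIM): early negative energy balance mobilises body fat, raising long-chain
fatty acids (C18:0, C18:1cis9, MUFA) in milk, while de novo medium-chain
synthesis (C10:0, C14:0, C16:0, SAT) recovers later. Cows with subclinical
ketosis (blood β-hydroxybutyrate, BHB > 1.0 ng/mL) show an exaggerated early
pattern — less C14:0, more C18:1cis9. `milkFTIR` is for researchers working
with dry-film FTIR spectra of milk who want a reproducible pipeline from raw
replicate spectra to those biological read-outs.

The core methods, in the field's standard notation:

* **Preprocessing** — Savitzky–Golay second derivative (window 13, degree 2,
  half-window ends dropped, scaled to absorbance/(cm⁻¹)²), wavenumber-region
  selection (3200–2800 and 1800–600 cm⁻¹), and EMSC: each spectrum *z* is fit
  by least squares as *z ≈ a + b·m + d·ν̃ + e·ν̃²* against a reference *m*,
  and corrected to *(z − a − d·ν̃ − e·ν̃²)/b*. Preprocessing precedes
  replicate averaging; the EMSC reference is frozen so prediction-time data
  are treated identically.
* **PLSR calibration** — single-response NIPALS PLS for nine fatty-acid
  features (% of total FA), with the LV count chosen as the smallest whose
  cross-validated RMSECV is within 2% of the curve minimum; pooled
  (segmented-CV) and independent test-set validation regimes.
* **Sparse PLS-DA** — DIM1 (5 ≤ DIM ≤ 50) vs DIM2 (50 < DIM ≤ 100)
  classification in which each latent variable's weight vector is
  hard-thresholded to its top ⌈(1−s)·p⌉ entries, with sparsity s ∈
  [0.90, 0.99] and 1–10 LVs optimised by leave-one-cow-out cross-validation;
  fitted on all samples and per parity group (PAR1, PAR2, PAR>2), summarised
  by correlation-loading plots.
* **Ketosis comparison** — per-DIM fatty-acid trajectories of ketotic vs
  normal cows, early-window (DIM ≤ 21) contrasts with seeded bootstrap CIs,
  and PCA of each cow's first 1/3/5 samples with three-tier BHB coding.
* **Synthetic cohort generator** — 61 cows, thrice-weekly sampling, triplicate
  spectra built from Gaussian band mixtures with multiplicative/polynomial
  baselines and known ground truth, so the entire stack is testable offline.

## Worked example

```r
library(milkFTIR)

cfg <- cohortConfig(nCows = 61, seed = 1)   # the study-design defaults
sim <- simulateCohort(cfg)
sim$spectra
#> SpectraSet with 7686 spectra x 1167 wavenumbers
#>   axis: 4000.0 .. 502.0 cm-1 (descending)
#>   cows: 61  DIM range: 5-100

qc <- qualityCheck(sim$spectra)
pp <- labelStageParity(preprocessPipeline(qc$spectra))
pp
#> SpectraSet with 2553 spectra x 534 wavenumbers
#>   axis: 3199.0 .. 601.0 cm-1 (descending)
#>   cows: 61  DIM range: 5-100
#>   stage labels: DIM1=1216 DIM2=1337
#>   preprocessed: yes (provenance attached)

ex <- exploreDIM(pp)                        # PCA of per-DIM average spectra
ex$pca
#> PCAModel: 3 components of 42
#>   explained: 85.0% 13.3% 0.6%
cor(ex$scores$dim, ex$scores$PC1, method = "spearman")
#> [1] 0.986
```

The first component of the DIM-averaged spectra tracks days in milk almost
monotonically (Spearman 0.99): milk drifts along one dominant compositional
axis through early lactation.

```r
faRef <- sim$truth[, c("sample_id", faFeatureNames())]
models <- calibrateFA(pp, faRef, seed = 2)  # pooled 10%-segment CV
models[["C18:1cis9"]]
#> PLSRModel for C18:1cis9 - 4 LV, 534 variables
#>   RMSECV 0.7646

pred <- predictFA(models, pp)
kc <- ketosisCompare(pred, sampleMeta(pp), sim$cows, seed = 3)
subset(kc$contrasts, feature %in% c("C14:0", "C18:0", "C18:1cis9"))
#>     feature   diff     lo     hi
#> 2     C14:0 -0.770 -1.104 -0.453
#> 4     C18:0  0.909  0.537  1.305
#> 5 C18:1cis9  1.742  1.014  2.502
```

A 4-LV PLSR predicts C18:1cis9 with RMSECV 0.76% of total FA. In the early
window (DIM ≤ 21) ketotic cows run 0.77 percentage points *lower* in C14:0
and 1.74 points *higher* in C18:1cis9 than normal cows, with bootstrap CIs
excluding zero — the fat-mobilisation signature that makes early detection
of subclinical ketosis from milk spectra plausible.

`runStudy(runConfig(seed = 1, outDir = "out"))` orchestrates all of the
above (simulation, quality check, preprocessing, DIM/parity PCA, both
calibration regimes, the four classification models, trajectories and the
ketosis comparison) and writes every table plus a manifest; runs are
byte-identical given the same seed. A thin shell wrapper is installed at
`inst/scripts/run_study.R`.

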