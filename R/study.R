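#' PLSR calibration of fatty-acid features
#'
#' Fits one PLS1 calibration per fatty-acid feature. Two validation regimes
#' are supported: `"pooled"` uses all calibration samples with random
#' segmented cross-validation (10% held out per loop) both to pick the number
#' of latent variables (smallest RMSECV within the parsimony band) and to
#' report RMSECV; `"testset"` restricts training to the samples *not* in
#' `testIds` and reports RMSEP/R2 on the held-out test samples.
#'
#' @param s preprocessed, replicate-averaged [SpectraSet-class] of the
#'   calibration samples.
#' @param faRef data.frame of reference fatty-acid values (first column
#'   `sample_id`), e.g. GC-FID results or generator truth.
#' @param regime `"pooled"` or `"testset"`.
#' @param testIds sample ids forming the independent test set (testset
#'   regime only).
#' @param maxLv largest latent-variable count considered (default 10).
#' @param fraction held-out fraction for the segmented CV (default 0.10).
#' @param seed seed for the random segments.
#' @return named list of [PLSRModel-class], one per feature, each carrying
#'   its validation metrics and the preprocessing provenance of `s`.
#' @export
calibrateFA <- function(s, faRef, regime = c("pooled", "testset"),
                        testIds = NULL, maxLv = 10L, fraction = 0.1,
                        seed = 1L) {
  regime <- match.arg(regime)
  ids <- sampleMeta(s)$sample_id
  ref <- faRef[match(ids, faRef$sample_id), , drop = FALSE]
  .stopIf(anyNA(ref$sample_id), "reference values missing for some samples")
  X <- absorbance(s)
  feats <- intersect(faFeatureNames(), colnames(ref))
  .stopIf(!length(feats), "no fatty-acid feature columns in faRef")
  trainIdx <- seq_len(nrow(X))
  testIdx <- integer()
  if (regime == "testset") {
    .stopIf(is.null(testIds), "testset regime needs testIds")
    testIdx <- which(ids %in% testIds)
    .stopIf(!length(testIdx), "no test samples found in s")
    trainIdx <- setdiff(trainIdx, testIdx)
  }
  Xt <- X[trainIdx, , drop = FALSE]
  split <- randomSegments(nrow(Xt), fraction, seed)
  models <- list()
  for (f in feats) {
    y <- as.numeric(ref[[f]])
    sel <- selectNLV(Xt, y[trainIdx], split, maxLv = maxLv)
    mod <- pls1Fit(Xt, y[trainIdx], nLv = sel$nLv, analyte = f,
                   provenance = provenance(s))
    metrics <- list(regime = regime, nLv = sel$nLv,
                    rmsecv = sel$rmsecvCurve[sel$nLv],
                    rmsecvCurve = sel$rmsecvCurve)
    if (regime == "testset") {
      v <- validateModel(mod, X[testIdx, , drop = FALSE], y[testIdx])
      metrics$rmsep <- v$rmsep
      metrics$r2 <- v$r2
    }
    mod@metrics <- metrics
    models[[f]] <- mod
  }
  models
}

#' Predict fatty-acid features for a spectral set
#'
#' @param models named list of [PLSRModel-class] from [calibrateFA()].
#' @param s a preprocessed [SpectraSet-class] on the models' variable set.
#' @return data.frame: `sample_id` plus one column per feature.
#' @export
predictFA <- function(models, s) {
  X <- absorbance(s)
  out <- data.frame(sample_id = sampleMeta(s)$sample_id)
  for (f in names(models)) out[[f]] <- predict(models[[f]], X)
  out
}

#' PCA of per-DIM average spectra
#'
#' Averages the spectra of all cows at each DIM, fits a PCA, and returns the
#' score-versus-DIM table together with the PC1-PC3 loadings — the standard
#' exploration of how milk composition drifts through lactation.
#'
#' @param s a preprocessed [SpectraSet-class].
#' @param k components to retain (default 3, capped by the data).
#' @return `list(pca = PCAModel, scores = data.frame(dim, PC...),
#'   loadings = data.frame(wavenumber, PC...))`.
#' @export
exploreDIM <- function(s, k = 3L) {
  avg <- averageBy(s, "dim")
  .stopIf(nrow(avg) < 3L, "need >= 3 distinct DIM values, got %d", nrow(avg))
  X <- as.matrix(avg[, -1L, drop = FALSE])
  k <- min(k, nrow(X) - 1L, ncol(X))
  pca <- pcaFit(X, k)
  scores <- data.frame(dim = avg$dim, pca@scores)
  loadings <- data.frame(wavenumber = as.numeric(colnames(avg)[-1L]),
                         t(pca@loadings))
  list(pca = pca, scores = scores, loadings = loadings)
}

#' PCA of per-parity average spectra
#'
#' As [exploreDIM()] but averaging all milk samples of each parity, giving
#' one score point per parity (1-6).
#'
#' @param s a preprocessed [SpectraSet-class].
#' @param k components to retain (capped by the number of parity levels).
#' @return `list(pca, scores, loadings)` with a `parity` score column.
#' @export
exploreParity <- function(s, k = 3L) {
  avg <- averageBy(s, "parity")
  .stopIf(nrow(avg) < 3L, "need >= 3 distinct parities, got %d", nrow(avg))
  X <- as.matrix(avg[, -1L, drop = FALSE])
  k <- min(k, nrow(X) - 1L, ncol(X))
  pca <- pcaFit(X, k)
  scores <- data.frame(parity = avg$parity, pca@scores)
  loadings <- data.frame(wavenumber = as.numeric(colnames(avg)[-1L]),
                         t(pca@loadings))
  list(pca = pca, scores = scores, loadings = loadings)
}

#' Fatty-acid trajectories over lactation
#'
#' Cohort-average and per-cow fatty-acid values at each DIM, the tables
#' behind trajectory plots of each feature against days in milk.
#'
#' @param fa per-sample feature table (first column `sample_id`).
#' @param meta sample metadata with `sample_id`, `cow_id`, `dim`.
#' @return `list(overall = data.frame(dim, features...),
#'   perCow = data.frame(cow_id, dim, features...))`.
#' @export
faTrajectories <- function(fa, meta) {
  overall <- averageBy(fa, "dim", meta)
  m <- meta[match(fa$sample_id, meta$sample_id), , drop = FALSE]
  key <- paste(m$cow_id, m$dim, sep = "\r")
  g <- factor(key, levels = unique(key))
  v <- as.matrix(fa[, -1L, drop = FALSE])
  xm <- rowsum(v, g, reorder = FALSE) / as.vector(table(g))
  first <- !duplicated(key)
  perCow <- data.frame(cow_id = m$cow_id[first], dim = m$dim[first], xm,
                       check.names = FALSE)
  perCow <- perCow[order(perCow$cow_id, perCow$dim), , drop = FALSE]
  rownames(perCow) <- NULL
  list(overall = overall, perCow = perCow)
}

#' Subclinical-ketosis comparison of fatty-acid features
#'
#' Splits cows at blood BHB > 1.0 ng/mL and computes (i) per-DIM group means
#' of every feature (the trajectory comparison of ketotic versus normal
#' cows), (ii) early-window contrasts (ketotic minus normal cow-level means
#' over DIM <= `earlyWindow`) with a seeded nonparametric bootstrap CI over
#' cows, and (iii) PCA of per-cow averages of the first k samples of each
#' lactation (k in `firstK`), with the three-tier BHB coding (<= 1.0,
#' (1.0, 2.0], > 2.0 ng/mL) attached to the scores. With fewer than two cows
#' in a group, contrasts are reported without CIs (warning); with a single
#' group, the comparison degenerates to a one-group summary.
#'
#' @param fa per-sample feature table (first column `sample_id`).
#' @param meta sample metadata (`sample_id`, `cow_id`, `dim`).
#' @param cows cow table from [cowRecords()]/[assignBHB()] (BHB required for
#'   all cows).
#' @param earlyWindow last DIM of the early-lactation window (default 21,
#'   aligning with blood sampling in week 3).
#' @param firstK sample counts for the first-k PCA (default 1, 3, 5).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param ciLevel CI level (default 0.95).
#' @return list with `groupMeans`, `contrasts`, `firstK`, `earlyWindow`.
#' @export
ketosisCompare <- function(fa, meta, cows, earlyWindow = 21L,
                           firstK = c(1L, 3L, 5L), nBoot = 1000L, seed = 1L,
                           ciLevel = 0.95) {
  m <- meta[match(fa$sample_id, meta$sample_id), , drop = FALSE]
  rec <- cows[match(m$cow_id, cows$cow_id), , drop = FALSE]
  .stopIf(anyNA(rec$bhb_ng_per_ml), "BHB missing for some cows")
  feats <- colnames(fa)[-1L]
  v <- as.matrix(fa[, -1L, drop = FALSE])
  grp <- ifelse(rec$ketosis, "ketotic", "normal")

  gm <- lapply(split(seq_len(nrow(v)), list(dim = m$dim, group = grp),
                     drop = TRUE),
               function(i) colMeans(v[i, , drop = FALSE]))
  keys <- do.call(rbind, strsplit(names(gm), ".", fixed = TRUE))
  groupMeans <- data.frame(dim = as.integer(keys[, 1L]), group = keys[, 2L],
                           do.call(rbind, gm), check.names = FALSE)
  groupMeans <- groupMeans[order(groupMeans$group, groupMeans$dim), ]
  rownames(groupMeans) <- NULL

  early <- which(m$dim <= earlyWindow)
  gEarly <- factor(m$cow_id[early], levels = unique(m$cow_id[early]))
  cowEarly <- rowsum(v[early, , drop = FALSE], gEarly, reorder = FALSE) /
    as.vector(table(gEarly))
  cowKeto <- cows$ketosis[match(levels(gEarly), cows$cow_id)]
  nK <- sum(cowKeto); nN <- sum(!cowKeto)
  contrasts <- NULL
  if (nK > 0L && nN > 0L) {
    diff <- colMeans(cowEarly[cowKeto, , drop = FALSE]) -
      colMeans(cowEarly[!cowKeto, , drop = FALSE])
    lo <- hi <- rep(NA_real_, length(feats))
    if (nK >= 2L && nN >= 2L) {
      kIdx <- which(cowKeto); nIdx <- which(!cowKeto)
      boots <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
        colMeans(cowEarly[sample(kIdx, nK, TRUE), , drop = FALSE]) -
          colMeans(cowEarly[sample(nIdx, nN, TRUE), , drop = FALSE])
      }, numeric(length(feats))))
      if (is.null(dim(boots))) boots <- matrix(boots, nrow = 1L)
      al <- (1 - ciLevel) / 2
      ci <- apply(boots, 1L, stats::quantile, probs = c(al, 1 - al))
      lo <- ci[1L, ]; hi <- ci[2L, ]
    } else {
      warning("a BHB group has < 2 cows; contrasts reported without CIs")
    }
    contrasts <- data.frame(feature = feats, diff = as.numeric(diff),
                            lo = lo, hi = hi, row.names = NULL)
  } else {
    warning("only one BHB group present; returning one-group summary")
  }

  km <- m[order(m$cow_id, m$dim), , drop = FALSE]
  vo <- v[order(m$cow_id, m$dim), , drop = FALSE]
  firstKOut <- list()
  for (k in firstK) {
    byCow <- split(seq_len(nrow(km)), km$cow_id)
    cm <- do.call(rbind, lapply(byCow, function(i)
      colMeans(vo[i[seq_len(min(k, length(i)))], , drop = FALSE])))
    rownames(cm) <- names(byCow)
    kk <- min(2L, nrow(cm) - 1L, ncol(cm))
    pca <- pcaFit(cm, kk)
    tier <- cows$tier[match(rownames(cm), cows$cow_id)]
    firstKOut[[as.character(k)]] <- list(
      pca = pca,
      scores = data.frame(cow_id = rownames(cm), pca@scores, tier = tier,
                          row.names = NULL))
  }
  list(groupMeans = groupMeans, contrasts = contrasts, firstK = firstKOut,
       earlyWindow = earlyWindow)
}

#' Study run configuration
#'
#' @param generator a [cohortConfig()] for the study cohort.
#' @param preprocess a [preprocessSpec()].
#' @param nCalibrationA samples simulated as the external calibration set
#'   (default 219).
#' @param nTestB study samples drawn at random into the calibration/test set
#'   (default 25).
#' @param classGrid a [splsdaGrid()].
#' @param earlyWindow early-lactation window for the ketosis contrasts.
#' @param bhbThresholds ketosis thresholds in ng/mL (must be positive and
#'   increasing; informational — the 1.0/2.0 rules live in [cowRecords()]).
#' @param maxLv largest PLSR latent-variable count.
#' @param seed master seed; every stage derives its randomness from it.
#' @param outDir output directory.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(generator = cohortConfig(), preprocess = preprocessSpec(),
                      nCalibrationA = 219L, nTestB = 25L,
                      classGrid = splsdaGrid(), earlyWindow = 21L,
                      bhbThresholds = c(1.0, 2.0), maxLv = 10L, seed = 1L,
                      outDir = tempfile("milkftir_run_")) {
  .stopIf(any(bhbThresholds <= 0) || diff(bhbThresholds) <= 0,
          "BHB thresholds must be positive and increasing")
  structure(list(generator = generator, preprocess = preprocess,
                 nCalibrationA = as.integer(nCalibrationA),
                 nTestB = as.integer(nTestB), classGrid = classGrid,
                 earlyWindow = as.integer(earlyWindow),
                 bhbThresholds = bhbThresholds, maxLv = as.integer(maxLv),
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  message(sprintf("[milkFTIR] stage: %s", name))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[milkFTIR] stage %s done (%.1f s)", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full desk-scale study
#'
#' Orchestrates: cohort simulation, spectral quality check, preprocessing,
#' DIM and parity PCA exploration, fatty-acid PLSR calibration (pooled-CV and
#' test-set regimes, with an independently simulated external calibration set
#' and a random test subset of the study cohort), prediction of all study
#' samples, the four lactation-stage classification models, and the
#' subclinical-ketosis comparison. All tables and a machine-readable manifest
#' are written to `cfg$outDir`; the run is fully deterministic given
#' `cfg$seed` (the manifest contains no timestamps, so repeated runs are
#' byte-identical). Stage timings go to the message stream.
#'
#' @param cfg a [runConfig()].
#' @return invisibly, a list with every intermediate result and `outDir`.
#' @export
runStudy <- function(cfg = runConfig()) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  gen <- cfg$generator
  gen$seed <- cfg$seed
  sim <- .stage("simulate", simulateCohort(gen))

  qc <- .stage("quality_check", qualityCheck(sim$spectra))
  pp <- .stage("preprocess",
               labelStageParity(preprocessPipeline(qc$spectra,
                                                   cfg$preprocess)))
  meta <- sampleMeta(pp)

  dimEx <- .stage("explore_dim", exploreDIM(pp))
  parEx <- .stage("explore_parity", exploreParity(pp))

  calib <- .stage("calibrate", {
    genA <- gen
    genA$seed <- cfg$seed + 101L
    genA$nCows <- max(8L, ceiling(cfg$nCalibrationA / length(gen$dims)) + 2L)
    simA <- simulateCohort(genA)
    # the external set comes from different animals: re-label its cows
    colData(simA$spectra)$cow_id <- sub("^cow", "cal",
                                        colData(simA$spectra)$cow_id)
    colData(simA$spectra)$sample_id <- sub("^cow", "cal",
                                           colData(simA$spectra)$sample_id)
    simA$truth$cow_id <- sub("^cow", "cal", simA$truth$cow_id)
    simA$truth$sample_id <- sub("^cow", "cal", simA$truth$sample_id)
    ppA <- applyProvenance(simA$spectra, provenance(pp))
    idsA <- .withSeed(cfg$seed + 102L,
                      sample(sampleMeta(ppA)$sample_id, cfg$nCalibrationA))
    idsB <- .withSeed(cfg$seed + 103L,
                      sample(meta$sample_id, cfg$nTestB))
    selA <- ppA[, which(sampleMeta(ppA)$sample_id %in% idsA)]
    selB <- pp[, which(meta$sample_id %in% idsB)]
    cols <- c("sample_id", "cow_id", "dim", "parity", "replicate")
    pool <- SpectraSet(rbind(absorbance(selA), absorbance(selB)),
                       wavenumbers(selA),
                       rbind(sampleMeta(selA)[, cols],
                             sampleMeta(selB)[, cols]))
    provenance(pool) <- provenance(pp)
    faRef <- rbind(simA$truth, sim$truth)
    pooled <- calibrateFA(pool, faRef, regime = "pooled", maxLv = cfg$maxLv,
                          seed = cfg$seed + 104L)
    testset <- calibrateFA(pool, faRef, regime = "testset", testIds = idsB,
                           maxLv = cfg$maxLv, seed = cfg$seed + 105L)
    list(pooled = pooled, testset = testset, idsA = idsA, idsB = idsB)
  })

  faPred <- .stage("predict", predictFA(calib$pooled, pp))
  classModels <- .stage("classify",
                        runClassModels(pp, faPred, grid = cfg$classGrid))
  traj <- .stage("trajectories", faTrajectories(faPred, meta))
  keto <- .stage("ketosis",
                 ketosisCompare(faPred, meta, sim$cows,
                                earlyWindow = cfg$earlyWindow,
                                seed = cfg$seed + 106L))

  .stage("write", {
    out <- cfg$outDir
    fw <- function(x, f) data.table::fwrite(x, file.path(out, f))
    fw(dimEx$scores, "dim_scores.csv")
    fw(dimEx$loadings, "dim_loadings.csv")
    fw(parEx$scores, "parity_scores.csv")
    fw(faPred, "fa_predictions.csv")
    fw(traj$overall, "trajectories_overall.csv")
    fw(traj$perCow, "trajectories_per_cow.csv")
    fw(keto$groupMeans, "ketosis_group_means.csv")
    if (!is.null(keto$contrasts)) fw(keto$contrasts, "ketosis_contrasts.csv")
    fk <- do.call(rbind, lapply(names(keto$firstK), function(k)
      cbind(k = as.integer(k), keto$firstK[[k]]$scores)))
    fw(fk, "ketosis_firstk_scores.csv")
    fw(sim$cows, "cows.csv")
    cl <- do.call(rbind, lapply(names(classModels), function(nm)
      cbind(group = nm, classModels[[nm]]$loadings)))
    fw(cl, "correlation_loadings.csv")
    cm <- do.call(rbind, lapply(names(classModels), function(nm) {
      m <- classModels[[nm]]$model
      data.frame(group = nm, nLv = m@nLv, sparsity = m@sparsity[1L],
                 cvAccuracy = m@cvAccuracy, nSelected = sum(m@selectedMask))
    }))
    fw(cm, "class_models.csv")
    met <- do.call(rbind, lapply(c("pooled", "testset"), function(r)
      do.call(rbind, lapply(calib[[r]], function(m)
        data.frame(analyte = m@analyte, regime = r, nLv = m@nLv,
                   rmsecv = m@metrics$rmsecv,
                   rmsep = if (is.null(m@metrics$rmsep)) NA_real_
                           else m@metrics$rmsep,
                   r2 = if (is.null(m@metrics$r2)) NA_real_
                        else m@metrics$r2)))))
    fw(met, "calibration_metrics.csv")
    cfgFile <- file.path(out, "config.json")
    cfgOut <- cfg
    cfgOut$generator$bands <- NULL
    cfgOut$generator$faParams <- NULL
    cfgOut$outDir <- NULL
    jsonlite::write_json(cfgOut, cfgFile, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    manifest <- list(
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(cfgFile)),
      package_version = as.character(utils::packageVersion("milkFTIR")),
      n_samples = nrow(meta), n_cows = length(unique(meta$cow_id)),
      tables = sort(setdiff(list.files(out), "manifest.json")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(list(sim = sim, qc = qc, preprocessed = pp, dim = dimEx,
                 parity = parEx, calibration = calib, faPred = faPred,
                 classModels = classModels, trajectories = traj,
                 ketosis = keto, outDir = cfg$outDir))
}
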