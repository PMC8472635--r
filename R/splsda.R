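#' Sparse PLS discriminant analysis grid
#'
#' Optimisation grid for [splsdaOptimize()]: sparsity levels 0.90..0.99
#' (fraction of variables *removed* per latent variable, so between 1% and
#' 10% of variables are retained per LV) and 1..10 latent variables.
#'
#' @param sparsity candidate sparsity levels.
#' @param nLv candidate latent-variable counts.
#' @param objective `"accuracy"` or `"balanced_accuracy"`.
#' @return a list of class `"splsdaGrid"`.
#' @export
splsdaGrid <- function(sparsity = seq(0.90, 0.99, by = 0.01), nLv = 1:10,
                       objective = c("accuracy", "balanced_accuracy")) {
  .stopIf(!length(sparsity) || !length(nLv), "empty optimisation grid")
  structure(list(sparsity = sparsity, nLv = as.integer(nLv),
                 objective = match.arg(objective)),
            class = "splsdaGrid")
}

# labels -> list(y01, classCode); first level codes to 0, second to 1
.codeLabels <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  .stopIf(nlevels(f) != 2L, "need exactly two classes, got %d", nlevels(f))
  list(y = as.numeric(f) - 1, classCode = levels(f))
}

#' Fit a sparse PLS-DA model at fixed settings
#'
#' Two-class PLS1-DA on the 0/1 dummy-coded labels. Per latent variable the
#' dense weight vector (proportional to X'y on the deflated data) is
#' hard-thresholded to its `ceiling((1 - sparsity) * p)` largest-magnitude
#' entries (floor of one variable), renormalised, and used as in ordinary
#' NIPALS PLS. `sparsity = 0` reduces exactly to dense PLS1-DA. The class is
#' predicted by thresholding the predicted dummy at `threshold`.
#'
#' @param X numeric matrix, samples by variables.
#' @param labels two-class factor (first level codes to 0).
#' @param nLv number of latent variables.
#' @param sparsity scalar or per-LV vector in `[0, 1)`.
#' @param threshold decision threshold on the predicted dummy (default 0.5).
#' @param provenance optional preprocessing provenance to store.
#' @return a [SPLSDAModel-class].
#' @export
splsdaFit <- function(X, labels, nLv, sparsity, threshold = 0.5,
                      provenance = list()) {
  X <- as.matrix(X)
  cl <- .codeLabels(labels)
  .stopIf(length(cl$y) != nrow(X), "labels/rows mismatch")
  p <- ncol(X)
  sparsity <- rep_len(sparsity, nLv)
  keep <- vapply(sparsity, .keepCount, 1L, p = p)
  mu <- colMeans(X); ybar <- mean(cl$y)
  Xc <- sweep(X, 2L, mu)
  fit <- .kpls1(crossprod(Xc), as.numeric(crossprod(Xc, cl$y - ybar)),
                nLv, keep = keep)
  B <- as.numeric(fit$R %*% fit$q)
  new("SPLSDAModel", nLv = fit$nLv, sparsity = sparsity[seq_len(fit$nLv)],
      classCode = cl$classCode, threshold = threshold,
      selectedMask = rowSums(abs(fit$W)) > 0,
      cvAccuracy = NA_real_, gridAccuracy = matrix(NA_real_, 0, 0),
      coefficients = B, intercept = ybar - sum(mu * B),
      xMeans = mu, yMean = ybar, weights = fit$W, loadingsX = fit$P,
      scoreCoef = fit$R, q = fit$q, provenance = provenance)
}

#' Predict classes (and dummy response / scores) from an SPLSDA model
#' @param object a [SPLSDAModel-class].
#' @param newdata matrix or [SpectraSet-class].
#' @param type `"class"`, `"response"` (predicted dummy) or `"scores"`.
#' @param ... ignored.
#' @export
setMethod("predict", "SPLSDAModel", function(object, newdata,
                                             type = c("class", "response",
                                                      "scores"), ...) {
  type <- match.arg(type)
  X <- if (is(newdata, "SpectraSet")) absorbance(newdata) else as.matrix(newdata)
  Xc <- sweep(X, 2L, object@xMeans)
  if (type == "scores") {
    Tm <- Xc %*% object@scoreCoef
    colnames(Tm) <- paste0("LV", seq_len(ncol(Tm)))
    return(Tm)
  }
  yhat <- as.numeric(object@intercept + X %*% object@coefficients)
  if (type == "response") return(yhat)
  factor(object@classCode[(yhat >= object@threshold) + 1L],
         levels = object@classCode)
})

# ---- grouped-CV engine ------------------------------------------------------
# Leave-one-group-out CV accuracies over an (nLv x sparsity) grid, computed
# through per-fold downdates of the full Gram matrix: M_fold = X'X -
# Xg'Xg (+ centring), so each fold costs O(ng p^2 + |grid| p^2) instead of
# O(n p^2) per grid cell. `precomp` lets callers (permutation nulls) reuse the
# full-data crossproduct.
.splsdaCvGrid <- function(X, y, foldIdx, nLvMax, sparsities, threshold = 0.5,
                          precomp = NULL, warnSkip = TRUE) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(precomp))
    precomp <- list(M = crossprod(X), cs = colSums(X))
  Sfull <- as.numeric(crossprod(X, y))
  ysum <- sum(y)
  nS <- length(sparsities)
  correct <- matrix(0, nLvMax, nS)
  correct0 <- correct1 <- matrix(0, nLvMax, nS)   # per-class, for balanced acc
  total <- 0L; total0 <- 0L; total1 <- 0L
  for (idx in foldIdx) {
    yg <- y[idx]
    ytr <- y[-idx]
    if (length(unique(ytr)) < 2L) {
      if (warnSkip) warning("fold skipped: single-class training data")
      next
    }
    Xg <- X[idx, , drop = FALSE]
    nf <- n - length(idx)
    mu <- (precomp$cs - colSums(Xg)) / nf
    Mc <- (precomp$M - crossprod(Xg)) - nf * tcrossprod(mu)
    ybar <- (ysum - sum(yg)) / nf
    Sc <- (Sfull - as.numeric(crossprod(Xg, yg))) - nf * mu * ybar
    for (j in seq_len(nS)) {
      fit <- .kpls1(Mc, Sc, nLvMax, keep = .keepCount(sparsities[j], p))
      Yh <- .kplsNestedPredict(fit, Xg, mu, ybar, nLvMax)
      pred <- Yh >= threshold
      hit <- pred == matrix(yg == 1, length(yg), nLvMax)
      correct[, j] <- correct[, j] + colSums(hit)
      correct0[, j] <- correct0[, j] + colSums(hit[yg == 0, , drop = FALSE])
      correct1[, j] <- correct1[, j] + colSums(hit[yg == 1, , drop = FALSE])
    }
    total <- total + length(idx)
    total0 <- total0 + sum(yg == 0); total1 <- total1 + sum(yg == 1)
  }
  .stopIf(total == 0L, "every CV fold was skipped")
  list(accuracy = correct / total,
       balanced = (correct0 / max(total0, 1) + correct1 / max(total1, 1)) / 2,
       total = total)
}

#' Optimise sparsity and latent-variable count under leave-one-cow-out CV
#'
#' For every grid cell, computes the grouped cross-validated classification
#' accuracy (each group's samples predicted by a model trained on all other
#' groups), then refits on all data at the best cell. Ties are broken toward
#' fewer latent variables, then higher sparsity. Folds whose training data
#' contain a single class are skipped with a warning.
#'
#' @param X numeric matrix, samples by variables.
#' @param labels two-class factor.
#' @param groups grouping vector (e.g. cow ids), same length as labels.
#' @param grid a [splsdaGrid()].
#' @param threshold decision threshold (default 0.5).
#' @param provenance optional provenance stored in the refit model.
#' @return a [SPLSDAModel-class] refit on all data, with `cvAccuracy` and the
#'   full `gridAccuracy` matrix (LV by sparsity) attached.
#' @export
splsdaOptimize <- function(X, labels, groups, grid = splsdaGrid(),
                           threshold = 0.5, provenance = list()) {
  X <- as.matrix(X)
  cl <- .codeLabels(labels)
  g <- factor(groups)
  .stopIf(length(g) != nrow(X), "groups/rows mismatch")
  .stopIf(nlevels(g) < 2L, "need at least two groups for grouped CV")
  foldIdx <- split(seq_len(nrow(X)), g)
  nLvMax <- max(grid$nLv)
  cv <- .splsdaCvGrid(X, cl$y, foldIdx, nLvMax, grid$sparsity, threshold)
  acc <- if (grid$objective == "balanced_accuracy") cv$balanced else cv$accuracy
  acc <- acc[grid$nLv, , drop = FALSE]
  dimnames(acc) <- list(paste0("LV", grid$nLv), as.character(grid$sparsity))
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1L], -best[, 2L]), , drop = FALSE][1L, ]
  nLvOpt <- grid$nLv[best[1L]]
  sOpt <- grid$sparsity[best[2L]]
  model <- splsdaFit(X, labels, nLv = nLvOpt, sparsity = sOpt,
                     threshold = threshold, provenance = provenance)
  model@cvAccuracy <- acc[best[1L], best[2L]]
  model@gridAccuracy <- acc
  model
}

#' Within-group label-permutation null for the grouped CV accuracy
#'
#' Repeatedly permutes the class labels within each group and recomputes the
#' leave-one-group-out CV accuracy at fixed `(nLv, sparsity)`. Under the null
#' of no class signal the accuracies centre on chance.
#'
#' @param X,labels,groups as in [splsdaOptimize()].
#' @param nLv,sparsity fixed model settings.
#' @param nPerm number of permutations (default 20).
#' @param seed integer seed.
#' @return numeric vector of permuted CV accuracies.
#' @export
splsdaPermutationNull <- function(X, labels, groups, nLv, sparsity,
                                  nPerm = 20L, seed = 1L) {
  X <- as.matrix(X)
  cl <- .codeLabels(labels)
  g <- factor(groups)
  foldIdx <- split(seq_len(nrow(X)), g)
  precomp <- list(M = crossprod(X), cs = colSums(X))
  .withSeed(seed, vapply(seq_len(nPerm), function(i) {
    yp <- cl$y
    for (idx in foldIdx) yp[idx] <- sample(yp[idx])
    cvp <- .splsdaCvGrid(X, yp, foldIdx, nLv, sparsity, precomp = precomp,
                         warnSkip = FALSE)
    cvp$accuracy[nLv, 1L]
  }, 1.0))
}

#' Fit the four lactation-stage classification models
#'
#' Fits DIM1-vs-DIM2 sparse PLS-DA models on all samples together and on the
#' PAR1, PAR2 and PAR>2 parity groups separately, each optimised under
#' leave-one-cow-out CV, and builds correlation loadings of the selected
#' spectral variables, the predicted fatty-acid features, and the 0/1 design
#' indicators (stage and parity-group membership) against the first two LV
#' score vectors.
#'
#' @param s a preprocessed, replicate-averaged, stage/parity-labelled
#'   [SpectraSet-class].
#' @param faPred data.frame of per-sample fatty-acid features (first column
#'   `sample_id`), typically PLSR predictions.
#' @param grid a [splsdaGrid()].
#' @param minGroup smallest parity-group size fitted; smaller groups are
#'   skipped with a warning (default 30).
#' @param maxSpectralVars at most this many evenly spaced spectral variables
#'   enter the correlation-loading table (display economy only; the model
#'   always uses all variables).
#' @return named list (`all`, `PAR1`, `PAR2`, `PARgt2`) of
#'   `list(model, loadings)`; skipped groups are absent.
#' @export
runClassModels <- function(s, faPred, grid = splsdaGrid(), minGroup = 30L,
                           maxSpectralVars = 60L) {
  cd <- sampleMeta(s)
  .stopIf(is.null(cd$stage) || is.null(cd$parity_group),
          "stage/parity labels missing; run labelStageParity() first")
  X <- absorbance(s)
  fa <- as.matrix(faPred[match(cd$sample_id, faPred$sample_id), -1L,
                         drop = FALSE])
  subsets <- list(all = seq_len(nrow(cd)),
                  PAR1 = which(cd$parity_group == "PAR1"),
                  PAR2 = which(cd$parity_group == "PAR2"),
                  PARgt2 = which(cd$parity_group == "PARgt2"))
  out <- list()
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]
    if (length(idx) < minGroup) {
      warning(sprintf("group %s has %d samples (< %d); skipped",
                      nm, length(idx), minGroup))
      next
    }
    if (length(unique(cd$cow_id[idx])) < 2L ||
        length(unique(cd$stage[idx])) < 2L) {
      warning(sprintf(
        "group %s lacks two cows or two stages; skipped", nm))
      next
    }
    model <- splsdaOptimize(X[idx, , drop = FALSE], cd$stage[idx],
                            cd$cow_id[idx], grid = grid,
                            provenance = provenance(s))
    scoreModel <- if (model@nLv >= 2L) model else
      splsdaFit(X[idx, , drop = FALSE], cd$stage[idx], nLv = 2L,
                sparsity = model@sparsity[1L])
    Tm <- predict(scoreModel, X[idx, , drop = FALSE], type = "scores")
    specIdx <- which(model@selectedMask)
    if (!length(specIdx)) specIdx <- seq_len(ncol(X))
    if (length(specIdx) > maxSpectralVars)
      specIdx <- specIdx[unique(round(seq(1, length(specIdx),
                                          length.out = maxSpectralVars)))]
    design <- cbind(DIM1 = as.numeric(cd$stage[idx] == "DIM1"),
                    DIM2 = as.numeric(cd$stage[idx] == "DIM2"),
                    PAR1 = as.numeric(cd$parity_group[idx] == "PAR1"),
                    PAR2 = as.numeric(cd$parity_group[idx] == "PAR2"),
                    PARgt2 = as.numeric(cd$parity_group[idx] == "PARgt2"))
    vars <- cbind(X[idx, specIdx, drop = FALSE], fa[idx, , drop = FALSE],
                  design)
    cls <- c(rep("spectral", length(specIdx)), rep("FA", ncol(fa)),
             rep("design", ncol(design)))
    out[[nm]] <- list(model = model,
                      loadings = correlationLoadings(Tm[, 1:2], vars, cls))
  }
  out
}
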