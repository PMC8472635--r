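#' Principal component analysis by SVD
#'
#' Column-mean-centred PCA. Explained fractions are singular values squared
#' over their total; the sign convention (largest-magnitude loading element
#' positive per component) makes results deterministic.
#'
#' @param X numeric matrix, observations by variables (n >= 2).
#' @param k number of components to retain (`<= min(n-1, p)`).
#' @return a [PCAModel-class].
#' @export
pcaFit <- function(X, k = 2L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  .stopIf(n < 2L, "PCA needs at least 2 observations")
  .stopIf(k > min(n - 1L, p), "k = %d exceeds min(n-1, p) = %d",
          k, min(n - 1L, p))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  .stopIf(tot < 1e-12 * max(1, sum(ctr^2)) || tot == 0,
          "X has (numerically) zero variance; PCA undefined")
  explained <- sv$d^2 / tot
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  load <- t(sv$v[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) {
      load[i, ] <- -load[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  rownames(load) <- colnames(scores) <- paste0("PC", seq_len(k))
  colnames(load) <- colnames(X)
  rownames(scores) <- rownames(X)
  new("PCAModel", scores = scores, loadings = load,
      explainedFraction = explained, center = ctr)
}

# ---- kernel PLS1 core -------------------------------------------------------
# NIPALS PLS1 expressed on the centred Gram quantities M = Xc'Xc (p x p) and
# S = Xc'yc (p). Per LV: w ~ S (optionally hard-thresholded to `keep` largest
# |entries| and renormalised), t = Xc w, p_a = M w / t't, q_a = S'w / t't;
# deflation updates S and M only, so the cost is p^2 per LV regardless of n.
# R = W (P'W)^{-1} maps centred X to scores; B_k = R[,1:k] q[1:k].
.kpls1 <- function(M, S, nLv, keep = NULL) {
  p <- length(S)
  W <- P <- R <- matrix(0, p, nLv)
  q <- numeric(nLv)
  a <- 0L
  scaleRef <- max(diag(M), 1e-300)
  for (l in seq_len(nLv)) {
    w <- as.numeric(S)
    if (!is.null(keep)) {
      kk <- if (length(keep) >= l) keep[l] else keep[length(keep)]
      if (kk < p) w[-order(abs(w), decreasing = TRUE)[seq_len(kk)]] <- 0
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(scaleRef)) break
    w <- w / nw
    Mw <- as.numeric(M %*% w)
    tt <- sum(w * Mw)
    if (tt < 1e-12 * scaleRef) break
    pa <- Mw / tt
    qa <- sum(S * w) / tt
    r <- w
    if (l > 1L)
      r <- w - R[, seq_len(l - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(l - 1L), drop = FALSE], w)
    a <- l
    W[, l] <- w; P[, l] <- pa; R[, l] <- r; q[l] <- qa
    S <- S - pa * (qa * tt)
    M <- M - tt * tcrossprod(pa)
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       R = R[, seq_len(a), drop = FALSE], q = q[seq_len(a)], nLv = a)
}

# nested predictions: ybar + cumsum over LVs of t_a q_a for centred Xv
# returns n x A matrix (column k = prediction using k LVs); if the fit stopped
# early, higher-k columns repeat the last available prediction.
.kplsNestedPredict <- function(fit, Xv, mu, ybar, nLvOut) {
  Tm <- sweep(Xv, 2L, mu) %*% fit$R
  C <- sweep(Tm, 2L, fit$q, `*`)
  Yh <- ybar + t(apply(C, 1L, cumsum))
  if (fit$nLv == 1L) Yh <- t(Yh)            # apply() drops to a vector
  if (nLvOut > fit$nLv)
    Yh <- cbind(Yh, matrix(Yh[, fit$nLv], nrow(Yh), nLvOut - fit$nLv))
  Yh
}

#' Fit a single-response PLS regression model
#'
#' NIPALS PLS1 with internal centring of X and y. When y is an exact linear
#' function of X and `nLv` reaches the required rank, the fit reproduces y
#' exactly; with `nLv = min(n-1, p)` on full-rank data the coefficients equal
#' the least-squares solution.
#'
#' @param X numeric matrix, observations by variables.
#' @param y numeric response.
#' @param nLv number of latent variables (truncated with a warning if it
#'   exceeds the achievable rank).
#' @param analyte response name carried in the model.
#' @param provenance optional preprocessing provenance to store.
#' @return a [PLSRModel-class].
#' @export
pls1Fit <- function(X, y, nLv, analyte = "y", provenance = list()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  .stopIf(length(y) != n, "length(y) = %d but X has %d rows", length(y), n)
  .stopIf(n <= nLv, "need n > nLv (n = %d, nLv = %d)", n, nLv)
  .stopIf(stats::var(y) < 1e-24, "zero-variance response")
  mu <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, mu)
  M <- crossprod(Xc)
  S <- as.numeric(crossprod(Xc, y - ybar))
  fit <- .kpls1(M, S, nLv)
  if (fit$nLv < nLv)
    warning(sprintf("nLv truncated from %d to %d (rank exhausted)",
                    nLv, fit$nLv))
  B <- as.numeric(fit$R %*% fit$q)
  new("PLSRModel", analyte = analyte, nLv = fit$nLv, coefficients = B,
      intercept = ybar - sum(mu * B), xMeans = mu, yMean = ybar,
      weights = fit$W, loadingsX = fit$P, scoreCoef = fit$R, q = fit$q,
      metrics = list(), provenance = provenance)
}

#' Predict from a PLSRModel
#' @param object a [PLSRModel-class].
#' @param newdata matrix (samples by variables) or [SpectraSet-class] on the
#'   model's variable set.
#' @param nLv number of latent variables to use (default: the model's).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata,
                                           nLv = object@nLv, ...) {
  X <- if (is(newdata, "SpectraSet")) absorbance(newdata) else as.matrix(newdata)
  .stopIf(ncol(X) != length(object@coefficients),
          "newdata has %d variables, model expects %d",
          ncol(X), length(object@coefficients))
  if (nLv == object@nLv) {
    as.numeric(object@intercept + X %*% object@coefficients)
  } else {
    .stopIf(nLv > object@nLv, "model holds only %d LVs", object@nLv)
    B <- as.numeric(object@scoreCoef[, seq_len(nLv), drop = FALSE] %*%
                      object@q[seq_len(nLv)])
    as.numeric(object@yMean - sum(object@xMeans * B) + X %*% B)
  }
})

#' Choose the number of latent variables by cross-validation
#'
#' Computes RMSECV over the split for 1..`maxLv` latent variables and returns
#' the smallest count whose RMSECV is within 2% of the minimum (a parsimony
#' band: the flat part of the error curve is entered at the earliest point).
#'
#' @param X,y training data.
#' @param split a [GroupedSplit-class] over the rows of `X`.
#' @param maxLv largest candidate (default 10).
#' @param band parsimony band (default 0.02).
#' @return `list(nLv, rmsecvCurve)`.
#' @export
selectNLV <- function(X, y, split, maxLv = 10L, band = 0.02) {
  X <- as.matrix(X); y <- as.numeric(y)
  .stopIf(maxLv < 1L, "maxLv must be >= 1")
  maxLv <- min(maxLv, ncol(X),
               min(vapply(split@segments, function(s) length(s$train), 1L)) - 1L)
  sse <- numeric(maxLv); nval <- 0L
  for (seg in split@segments) {
    Xt <- X[seg$train, , drop = FALSE]; yt <- y[seg$train]
    mu <- colMeans(Xt); ybar <- mean(yt)
    Xc <- sweep(Xt, 2L, mu)
    fit <- .kpls1(crossprod(Xc), as.numeric(crossprod(Xc, yt - ybar)), maxLv)
    Yh <- .kplsNestedPredict(fit, X[seg$validation, , drop = FALSE],
                             mu, ybar, maxLv)
    sse <- sse + colSums((Yh - y[seg$validation])^2)
    nval <- nval + length(seg$validation)
  }
  curve <- sqrt(sse / nval)
  nLv <- which(curve <= (1 + band) * min(curve))[1L]
  list(nLv = as.integer(nLv), rmsecvCurve = curve)
}

#' Validate a fitted model on an independent test set
#'
#' @param model a [PLSRModel-class] (or any object with a `predict` method
#'   returning a numeric vector).
#' @param X,y test predictors and reference values (preprocessed with the
#'   training provenance).
#' @return `list(rmsep, r2)`; R-squared is computed against the test-set mean.
#' @export
validateModel <- function(model, X, y) {
  y <- as.numeric(y)
  yhat <- predict(model, X)
  .stopIf(length(yhat) != length(y), "prediction/reference length mismatch")
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  list(rmsep = sqrt(mean((y - yhat)^2)), r2 = 1 - sse / sst)
}

#' Correlation loadings of variables against two score vectors
#'
#' Pearson correlation of each variable with the first two score vectors of a
#' bilinear model; 0/1 design indicators are handled identically (giving
#' point-biserial correlations). Zero-variance variables are returned as
#' (0, 0) and flagged rather than erroring. When the score vectors are
#' uncorrelated (as PCA/PLS scores are), every point lies inside the unit
#' circle; the conventional inner circle at sqrt(0.5) marks 50% explained.
#'
#' @param scores numeric matrix with >= 2 columns (only the first two used).
#' @param variables numeric matrix, same row count, one column per variable.
#' @param varClass optional character vector classifying each variable
#'   (e.g. "spectral", "FA", "design").
#' @return data.frame with columns `variable`, `r1`, `r2`, `class`, `flagged`.
#' @export
correlationLoadings <- function(scores, variables, varClass = NULL) {
  scores <- as.matrix(scores); variables <- as.matrix(variables)
  .stopIf(ncol(scores) < 2L, "need two score vectors")
  .stopIf(nrow(scores) != nrow(variables), "row count mismatch")
  sdv <- apply(variables, 2L, stats::sd)
  flagged <- sdv < 1e-12 | !is.finite(sdv)
  r <- matrix(0, ncol(variables), 2L)
  if (any(!flagged))
    r[!flagged, ] <- t(stats::cor(scores[, 1:2], variables[, !flagged,
                                                           drop = FALSE]))
  vn <- colnames(variables)
  if (is.null(vn)) vn <- paste0("V", seq_len(ncol(variables)))
  data.frame(variable = vn, r1 = r[, 1L], r2 = r[, 2L],
             class = if (is.null(varClass)) "variable" else varClass,
             flagged = flagged)
}
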