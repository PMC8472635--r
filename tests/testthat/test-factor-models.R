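test_that("PCA handles rank-1 data and reconstructs exactly", {
  withr::with_seed(2, {
    t_ <- rnorm(15); v <- rnorm(6); v <- v / sqrt(sum(v^2))
    X <- tcrossprod(t_, v) + matrix(rep(rnorm(6), each = 15), 15)
    p <- pcaFit(X, 1)
    expect_equal(p@explainedFraction[1], 1, tolerance = 1e-10)
    expect_equal(abs(sum(p@loadings[1, ] * v)), 1, tolerance = 1e-10)
    # full reconstruction
    X2 <- matrix(rnorm(15 * 6), 15)
    pf <- pcaFit(X2, 6)
    rec <- sweep(pf@scores %*% pf@loadings, 2, pf@center, `+`)
    expect_equal(rec, X2, ignore_attr = TRUE, tolerance = 1e-8)
  })
  expect_error(pcaFit(matrix(1, 5, 3), 1), "zero variance")
  expect_error(pcaFit(matrix(rnorm(6), 2, 3), 2), "exceeds")
})

test_that("PCA explained fractions match the covariance eigendecomposition", {
  X <- withr::with_seed(7, matrix(rnorm(20 * 50), 20))
  p <- pcaFit(X, 5)
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(p@explainedFraction[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-10)
  # invariant to row order and global scale
  p2 <- pcaFit(X[sample(20), ], 5)
  p3 <- pcaFit(X * 17.3, 5)
  expect_equal(p2@explainedFraction, p@explainedFraction, tolerance = 1e-10)
  expect_equal(p3@explainedFraction, p@explainedFraction, tolerance = 1e-10)
  # deterministic sign convention
  expect_true(all(apply(p@loadings, 1, function(l) l[which.max(abs(l))] > 0)))
})

test_that("averageBy equals a brute-force group-by mean in ascending key order", {
  s <- toySet(6, cow = rep(c("a", "b"), 3), dim = c(9, 9, 5, 5, 7, 7),
              replicate = rep(1:3, each = 2))
  got <- averageBy(s, "dim")
  expect_equal(got$dim, c(5, 7, 9))
  ref <- aggregate(absorbance(s), list(dim = sampleMeta(s)$dim), mean)
  expect_equal(as.matrix(got[, -1]), as.matrix(ref[, -1]), ignore_attr = TRUE)
  # single sample per level: identity
  s1 <- toySet(3, dim = c(5, 7, 9))
  expect_equal(unname(as.matrix(averageBy(s1, "dim")[, -1])),
               unname(absorbance(s1)))
  # feature-table method
  fa <- data.frame(sample_id = sampleMeta(s)$sample_id,
                   f1 = 1:6, f2 = c(2, 4, 6, 8, 10, 12))
  gotFA <- averageBy(fa, "cow_id", meta = sampleMeta(s))
  refFA <- aggregate(fa[, -1], list(sampleMeta(s)$cow_id), mean)
  expect_equal(gotFA$f1, refFA$f1)
  expect_error(averageBy(s, "bogus"), "key")
})

test_that("PLS1 recovers exact linear responses and the least-squares limit", {
  withr::with_seed(4, {
    X <- matrix(rnorm(40 * 8), 40)
    y <- drop(X %*% rnorm(8)) + 2
    m <- pls1Fit(X, y, 8)
    expect_lt(max(abs(predict(m, X) - y)), 1e-8)
    ls <- coef(lm(y ~ X))
    expect_equal(m@coefficients, unname(ls[-1]), tolerance = 1e-6)
    expect_equal(m@intercept, unname(ls[1]), tolerance = 1e-6)
    # low-rank X: nLv truncates with a warning
    Xl <- X[, 1:3] %*% matrix(rnorm(3 * 10), 3)
    yl <- drop(Xl %*% rnorm(10))
    expect_warning(ml <- pls1Fit(Xl, yl, 8), "truncated")
    expect_lt(max(abs(predict(ml, Xl) - yl)), 1e-6)
  })
  expect_error(pls1Fit(matrix(rnorm(20), 10), rep(1, 10), 1), "zero-variance")
})

test_that("one-LV PLS1 points along the covariance direction X'y", {
  withr::with_seed(9, for (i in 1:5) {
    X <- matrix(rnorm(30 * 12), 30)
    y <- rnorm(30)
    m <- pls1Fit(X, y, 1)
    Xc <- scale(X, scale = FALSE)
    s <- drop(crossprod(Xc, y - mean(y)))
    cosang <- sum(m@coefficients * s) /
      sqrt(sum(m@coefficients^2) * sum(s^2))
    expect_gte(cosang, 1 - 1e-8)
  })
})

test_that("the kernel engine matches naive NIPALS with X deflation", {
  withr::with_seed(14, {
    X <- matrix(rnorm(35 * 20), 35)
    y <- drop(X[, 1:4] %*% c(1, -2, 0.5, 1)) + rnorm(35, sd = 0.3)
    m <- pls1Fit(X, y, 5)
    nv <- naivePls1(X, y, 5)
    expect_equal(m@coefficients, nv$coefficients, tolerance = 1e-9)
    expect_equal(m@intercept, nv$intercept, tolerance = 1e-9)
    expect_equal(abs(m@weights), abs(nv$W), tolerance = 1e-9)
  })
})

test_that("LV selection finds the intrinsic dimension and applies the parsimony band", {
  withr::with_seed(6, {
    T3 <- matrix(rnorm(80 * 3), 80)
    X <- T3 %*% matrix(rnorm(3 * 25), 3)
    y <- drop(T3 %*% c(2, -1, 0.7))
    sel <- selectNLV(X, y, randomSegments(80, 0.1, 5), maxLv = 8)
    expect_equal(sel$nLv, 3L)
    expect_lt(sel$rmsecvCurve[3], 0.02 * sd(y))
  })
  # pure-noise response: 1 LV chosen in most seeds
  picks <- vapply(1:50, function(i) withr::with_seed(100 + i, {
    X <- matrix(rnorm(40 * 15), 40)
    selectNLV(X, rnorm(40), randomSegments(40, 0.2, i), maxLv = 6)$nLv
  }), 1L)
  expect_gte(mean(picks == 1L), 0.8)
})

test_that("noise-only responses give nonpositive cross-validated R2 on average", {
  r2 <- vapply(1:50, function(i) withr::with_seed(200 + i, {
    X <- matrix(rnorm(30 * 10), 30)
    y <- rnorm(30)
    sp <- randomSegments(30, 0.2, i)
    pred <- numeric(30)
    for (seg in sp@segments) {
      m <- pls1Fit(X[seg$train, ], y[seg$train], 1)
      pred[seg$validation] <- predict(m, X[seg$validation, , drop = FALSE])
    }
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }), 1.0)
  expect_lte(mean(r2), 0)
})

test_that("validation metrics follow their defining formulas", {
  withr::with_seed(3, {
    X <- matrix(rnorm(20 * 5), 20)
    y <- drop(X %*% rnorm(5)) + rnorm(20)
    m <- pls1Fit(X, y, 5)
    v <- validateModel(m, X, y)
    yhat <- predict(m, X)
    expect_equal(v$rmsep, sqrt(mean((y - yhat)^2)))
    expect_equal(v$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
    # perfect predictor
    perfect <- m; yp <- predict(m, X)
    vp <- validateModel(m, X, yp)
    expect_equal(vp$rmsep, 0); expect_equal(vp$r2, 1)
  })
})

test_that("correlation loadings equal direct Pearson correlations inside the unit circle", {
  withr::with_seed(5, {
    # centred, mutually uncorrelated score vectors (as PCA/PLS scores are)
    t1 <- scale(rnorm(40))[, 1]
    t2 <- resid(lm(rnorm(40) ~ t1))
    Tm <- cbind(t1 * 3, t2 * 2)
    V <- cbind(v1 = Tm[, 1], v2 = -Tm[, 2],
               mix = Tm %*% c(1, 1) + rnorm(40),
               flat = rep(1, 40),
               bin = rep(0:1, 20))
    cl <- correlationLoadings(Tm, V)
    expect_equal(cl$r1[1], 1, tolerance = 1e-8)
    expect_equal(abs(cl$r2[1]), 0, tolerance = 1e-8)
    expect_equal(cl$r2[2], -1, tolerance = 1e-8)
    expect_true(cl$flagged[4])
    expect_equal(cl$r1[4], 0)
    for (j in c(1, 2, 3, 5)) {
      expect_equal(cl$r1[j], cor(V[, j], Tm[, 1]), tolerance = 1e-10)
      expect_equal(cl$r2[j], cor(V[, j], Tm[, 2]), tolerance = 1e-10)
    }
    expect_true(all(cl$r1^2 + cl$r2^2 <= 1 + 1e-8))
  })
})
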