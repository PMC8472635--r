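# shared builders and independent oracles for the test suite

# small SpectraSet built in code
toySet <- function(n = 4, wn = seq(1900, 1700, by = -4), seed = 1,
                   cow = rep("c1", n), dim = seq(5, length.out = n, by = 2),
                   parity = 1, replicate = 1) {
  x <- withr::with_seed(seed, matrix(rnorm(n * length(wn)), n))
  SpectraSet(x, wn, data.frame(sample_id = paste0("s", seq_len(n)),
                               cow_id = cow, dim = dim, parity = parity,
                               replicate = replicate))
}

# compact cohort used where full scale is unnecessary
smallCohortConfig <- function(seed = 1, nCows = 10, ...) {
  cohortConfig(nCows = nCows, dims = defaultSchedule()[seq(1, 41, by = 3)],
               grid = c(start = 4000, stop = 500, step = 12), seed = seed, ...)
}

# naive NIPALS PLS1 with explicit X deflation -- the independent counterpart
# of the package's Gram-kernel engine
naivePls1 <- function(X, y, nLv, keep = NULL) {
  mu <- colMeans(X); ybar <- mean(y)
  Xd <- sweep(X, 2, mu); yc <- y - ybar
  p <- ncol(X)
  W <- P <- matrix(0, p, nLv); q <- numeric(nLv)
  for (a in seq_len(nLv)) {
    w <- drop(crossprod(Xd, yc))
    if (!is.null(keep) && keep < p)
      w[-order(abs(w), decreasing = TRUE)[seq_len(keep)]] <- 0
    w <- w / sqrt(sum(w^2))
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    P[, a] <- drop(crossprod(Xd, t_)) / tt
    q[a] <- sum(yc * t_) / tt
    W[, a] <- w
    Xd <- Xd - tcrossprod(t_, P[, a])
  }
  R <- W %*% solve(crossprod(P, W))
  B <- drop(R %*% q)
  list(coefficients = B, intercept = ybar - sum(mu * B), W = W, P = P, q = q)
}

# per-window local polynomial fit: oracle for the SG derivative
sgOracle <- function(y, wn, window = 13, polyorder = 2) {
  h <- (window - 1) %/% 2
  n <- length(y)
  out <- numeric(n - 2 * h)
  for (c in (h + 1):(n - h)) {
    i <- (c - h):(c + h)
    fit <- lm(y[i] ~ poly(wn[i], polyorder, raw = TRUE))
    out[c - h] <- 2 * coef(fit)[3]
  }
  out
}

# independent normal-equations EMSC solve for a single spectrum
emscOracle <- function(z, wn, ref, degree = 2) {
  nu <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  D <- cbind(1, ref, outer(nu, seq_len(degree), `^`))
  cf <- solve(t(D) %*% D, t(D) %*% z)
  corrected <- (z - D[, -2, drop = FALSE] %*% cf[-2]) / cf[2]
  list(a = cf[1], b = cf[2], d = cf[3], e = cf[4],
       corrected = drop(corrected))
}
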