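# internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed means use (and advance) the current stream
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}

# number of variables kept per LV at sparsity s (guarding float fuzz,
# with the documented floor of one variable)
.keepCount <- function(sparsity, p) {
  k <- ceiling((1 - sparsity) * p - 1e-9)
  max(1L, min(p, as.integer(k)))
}

.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)
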