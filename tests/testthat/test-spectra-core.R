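test_that("spectra CSV pair round-trips through write/read unchanged", {
  wn <- seq(4000, 502, by = -6)            # 584-point instrument grid
  expect_length(wn, 584)
  s <- toySet(3, wn = wn)
  dir <- withr::local_tempdir()
  writeSpectra(s, file.path(dir, "x.csv"), file.path(dir, "m.csv"))
  s2 <- readSpectra(file.path(dir, "x.csv"), file.path(dir, "m.csv"))
  expect_equal(wavenumbers(s2), wavenumbers(s))
  expect_equal(unname(absorbance(s2)), unname(absorbance(s)))
  expect_equal(sampleMeta(s2)[names(sampleMeta(s))], sampleMeta(s))
})

test_that("ascending wavenumber input is reordered, values preserved per wavenumber", {
  wn <- seq(1000, 1100, by = 5)
  x <- matrix(seq_along(wn), 1)            # value i at wavenumber wn[i]
  s <- SpectraSet(x, wn, data.frame(sample_id = "s1", cow_id = "c", dim = 5,
                                    parity = 1, replicate = 1))
  expect_true(all(diff(wavenumbers(s)) < 0))
  for (j in seq_along(wn))
    expect_equal(absorbance(s)[1, which(wavenumbers(s) == wn[j])],
                 x[1, j], ignore_attr = TRUE)
})

test_that("malformed inputs give structured errors", {
  dir <- withr::local_tempdir()
  s <- toySet(3, wn = seq(1800, 1760, by = -4))
  writeSpectra(s, file.path(dir, "x.csv"), file.path(dir, "m.csv"))
  m <- read.csv(file.path(dir, "m.csv"))
  write.csv(m[1:2, ], file.path(dir, "m2.csv"), row.names = FALSE)
  expect_error(readSpectra(file.path(dir, "x.csv"), file.path(dir, "m2.csv")),
               "2 rows .* 3 rows")
  # duplicate (cow, dim, replicate) triple
  meta <- sampleMeta(s); meta$dim <- c(5, 5, 7)
  expect_error(SpectraSet(absorbance(s), wavenumbers(s), meta),
               "duplicate .*cow_id, dim, replicate")
  # metadata row-count mismatch at construction
  expect_error(SpectraSet(absorbance(s), wavenumbers(s), meta[1:2, ]),
               "2 rows")
})

test_that("filterDIM retains the closed window and is idempotent", {
  s <- toySet(5, dim = c(4, 5, 50, 100, 101))
  f <- filterDIM(s, 5, 100)
  expect_equal(sampleMeta(f)$dim, c(5, 50, 100))
  expect_equal(sampleMeta(filterDIM(f, 5, 100)), sampleMeta(f))
  expect_equal(sampleMeta(filterDIM(s, 50, 50))$dim, 50)
  expect_error(filterDIM(s, 10, 5), "low")
  expect_warning(filterDIM(s, 200, 300), "every sample")
})

test_that("filterDIM matches a brute-force count on random DIMs", {
  dims <- withr::with_seed(42, sample(1:120, 1000, replace = TRUE))
  meta <- data.frame(sample_id = paste0("s", 1:1000),
                     cow_id = paste0("c", 1:1000), dim = dims, parity = 1,
                     replicate = 1)
  s <- SpectraSet(matrix(0, 1000, 3), c(1800, 1794, 1788), meta)
  expect_equal(nSamples(filterDIM(s, 5, 100)), sum(dims >= 5 & dims <= 100))
})

test_that("stage and parity-group labels follow the boundary rules and tile the set", {
  s <- toySet(4, dim = c(50, 51, 5, 100), parity = c(1, 2, 3, 6))
  l <- sampleMeta(labelStageParity(s))
  expect_equal(as.character(l$stage), c("DIM1", "DIM2", "DIM1", "DIM2"))
  expect_equal(as.character(l$parity_group), c("PAR1", "PAR2", "PARgt2", "PARgt2"))
  expect_equal(sum(table(l$stage)), nrow(l))
  expect_false(any(is.na(l$stage)) || any(is.na(l$parity_group)))
  expect_error(labelStageParity(toySet(2, parity = c(0, 1))), "parity")
})

test_that("quality check flags sign-flipped and non-finite spectra only", {
  wn <- seq(1900, 1700, by = -4)
  base <- sin(wn / 25)
  x <- rbind(base, base, base, base, -base)
  meta <- data.frame(sample_id = paste0("s", 1:5), cow_id = paste0("c", 1:5),
                     dim = 5, parity = 1, replicate = 1)
  qc <- qualityCheck(SpectraSet(x, wn, meta))
  expect_equal(qc$rejected, "s5")
  # clean set: nothing rejected at z = 3
  sClean <- toySet(6, seed = 3)
  x2 <- absorbance(sClean) * 0.05 + matrix(base, 6, length(wn), byrow = TRUE)
  qc2 <- qualityCheck(SpectraSet(x2, wn, sampleMeta(sClean)), zThreshold = 3)
  expect_length(qc2$rejected, 0)
  # non-finite value rejects regardless of correlation
  x3 <- x2; x3[2, 10] <- NA
  qc3 <- qualityCheck(SpectraSet(x3, wn, sampleMeta(sClean)))
  expect_equal(qc3$rejected, "s2")
  # everything non-finite: threshold unusable
  x4 <- x2; x4[] <- Inf
  expect_error(qualityCheck(SpectraSet(x4, wn, sampleMeta(sClean))),
               "every sample")
})

test_that("replicate averaging is the group-wise arithmetic mean", {
  wn <- seq(1800, 1760, by = -4)
  x <- rbind(rep(1, 11), rep(2, 11), rep(3, 11))
  meta <- data.frame(sample_id = paste0("s", 1:3), cow_id = "c1", dim = 5,
                     parity = 1, replicate = 1:3)
  avg <- averageReplicates(SpectraSet(x, wn, meta))
  expect_equal(nSamples(avg), 1L)
  expect_equal(unname(absorbance(avg)[1, ]), rep(2, 11))
  expect_equal(sampleMeta(avg)$replicate, 0L)
  # identical replicates pass through unchanged
  xi <- rbind(x[1, ], x[1, ], x[1, ])
  avgi <- averageReplicates(SpectraSet(xi, wn, meta))
  expect_equal(unname(absorbance(avgi)[1, ]), x[1, ])
  # random triplicated set equals a brute-force group-by mean
  s <- withr::with_seed(5, {
    m <- expand.grid(replicate = 1:3, dim = c(5, 7, 9),
                     cow_id = c("a", "b"))
    m$sample_id <- paste0("s", seq_len(nrow(m)))
    m$parity <- 1
    SpectraSet(matrix(rnorm(18 * 11), 18), wn, m)
  })
  got <- averageReplicates(s)
  ref <- aggregate(absorbance(s),
                   by = list(cow = sampleMeta(s)$cow_id,
                             dim = sampleMeta(s)$dim), FUN = mean)
  gm <- sampleMeta(got)
  for (i in seq_len(nrow(ref)))
    expect_equal(unname(absorbance(got)[which(gm$cow_id == ref$cow[i] &
                                              gm$dim == ref$dim[i]), ]),
                 unname(as.matrix(ref[i, -(1:2)])[1, ]))
})

test_that("BHB thresholds are strict at 1.0 and the tiers split at 2.0", {
  cows <- cowRecords(data.frame(cow_id = paste0("c", 1:5), parity = 1,
                                bhb_ng_per_ml = c(0.4, 1.0, 1.5, 2.0, 2.5)))
  expect_equal(cows$ketosis, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.character(cows$tier),
               c("normal", "normal", "mid", "mid", "high"))
})

test_that("leave-one-cow-out split has one segment per cow and no leakage", {
  meta <- data.frame(cow_id = rep(paste0("cow", 1:22), each = 3))
  sp <- leaveOneGroupOut(meta, "cow_id")
  expect_length(sp@segments, 22L)
  val <- unlist(lapply(sp@segments, `[[`, "validation"))
  expect_setequal(val, seq_len(nrow(meta)))
  expect_false(anyDuplicated(val) > 0)
  for (seg in sp@segments) {
    expect_length(unique(meta$cow_id[seg$validation]), 1L)
    expect_false(unique(meta$cow_id[seg$validation]) %in%
                   meta$cow_id[seg$train])
  }
  expect_error(leaveOneGroupOut(data.frame(cow_id = rep("x", 5))), "one group")
})

test_that("random segments partition the samples with near-equal sizes", {
  sp <- randomSegments(244, 0.10, seed = 7)
  expect_length(sp@segments, 10L)
  sizes <- vapply(sp@segments, function(s) length(s$validation), 1L)
  expect_true(all(sizes %in% c(24L, 25L)))
  expect_setequal(unlist(lapply(sp@segments, `[[`, "validation")), 1:244)
  # seeded determinism
  expect_identical(randomSegments(244, 0.10, seed = 7)@segments, sp@segments)
  expect_false(identical(randomSegments(244, 0.10, seed = 8)@segments,
                         sp@segments))
  expect_error(randomSegments(5, 0.1), "smaller")
})

test_that("both splitters tile the index set over random configurations", {
  withr::with_seed(11, for (i in 1:100) {
    n <- sample(20:120, 1)
    if (i %% 2 == 0) {
      sp <- randomSegments(n, runif(1, 0.08, 0.5), seed = i)
    } else {
      meta <- data.frame(cow_id = sample(paste0("c", 1:8), n, replace = TRUE))
      if (length(unique(meta$cow_id)) < 2) meta$cow_id[1] <- "extra"
      sp <- leaveOneGroupOut(meta, "cow_id")
    }
    val <- unlist(lapply(sp@segments, `[[`, "validation"))
    expect_setequal(val, seq_len(n))
    expect_equal(length(val), n)
  })
})
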