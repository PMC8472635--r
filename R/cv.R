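#' Leave-one-group-out cross-validation split
#'
#' One segment per distinct value of `groupKey` (typically `cow_id`, giving
#' leave-one-cow-out: at each step all samples of one cow are removed from the
#' training set and predicted). Validation sets tile the sample index set and
#' no group ever appears on both sides of a segment.
#'
#' @param meta data.frame of sample metadata.
#' @param groupKey metadata column to group by (default `"cow_id"`).
#' @return a [GroupedSplit-class].
#' @export
leaveOneGroupOut <- function(meta, groupKey = "cow_id") {
  meta <- as.data.frame(meta)
  .stopIf(!groupKey %in% colnames(meta), "no column '%s' in meta", groupKey)
  g <- meta[[groupKey]]
  .stopIf(anyNA(g), "grouping column '%s' contains NA", groupKey)
  lev <- unique(g)
  .stopIf(length(lev) < 2L,
          "only one group ('%s'); grouped validation impossible", lev[1L])
  idx <- seq_len(nrow(meta))
  segs <- lapply(lev, function(l)
    list(train = idx[g != l], validation = idx[g == l]))
  new("GroupedSplit", segments = segs, groupKey = groupKey)
}

#' Random segmented cross-validation split
#'
#' Splits `n` samples into `ceiling(1/fraction)` random segments whose sizes
#' differ by at most one (e.g. 244 samples at fraction 0.10 give 10 segments
#' of 24 or 25). Deterministic given `seed`.
#'
#' @param n number of samples.
#' @param fraction held-out fraction per segment, in (0, 1).
#' @param seed integer seed.
#' @return a [GroupedSplit-class] with `groupKey = "random"`.
#' @export
randomSegments <- function(n, fraction = 0.1, seed = 1L) {
  .stopIf(fraction <= 0 || fraction >= 1, "fraction must be in (0,1), got %s",
          fraction)
  nseg <- as.integer(ceiling(1 / fraction - 1e-9))
  .stopIf(n < nseg, "n = %d is smaller than the number of segments (%d)",
          n, nseg)
  perm <- .withSeed(seed, sample.int(n))
  sizes <- rep(n %/% nseg, nseg)
  extra <- n %% nseg
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-nseg] + 1L)
  idx <- seq_len(n)
  segs <- lapply(seq_len(nseg), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = setdiff(idx, val), validation = val)
  })
  new("GroupedSplit", segments = segs, groupKey = "random")
}
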