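# Independent brute-force oracles and small fixture builders.
# All oracles deliberately use the most literal possible computation
# (per-record loops, per-base-pair accumulation) so that they share no
# code path with the implementations they check.

# dense matrix from sparse records, one record at a time
brute_normalize <- function(records, kr, region, resolution) {
  n <- ceiling((region$end - region$start) / resolution)
  out <- matrix(0, n, n)
  agg <- list()
  for (r in seq_len(nrow(records))) {
    i <- records$i[r]; j <- records$j[r]
    if (i < region$start || i >= region$end ||
        j < region$start || j >= region$end) next
    bi <- (i - region$start) %/% resolution + 1
    bj <- (j - region$start) %/% resolution + 1
    key <- paste(min(bi, bj), max(bi, bj))
    agg[[key]] <- (if (is.null(agg[[key]])) 0 else agg[[key]]) +
      records$count[r]
  }
  for (key in names(agg)) {
    bb <- as.integer(strsplit(key, " ")[[1]])
    ai <- (region$start %/% resolution) + bb[1]   # absolute bin, 1-based
    aj <- (region$start %/% resolution) + bb[2]
    ki <- kr[ai]; kj <- kr[aj]
    v <- if (is.na(ki) || is.na(kj) || ki <= 0 || kj <= 0) NA_real_
         else agg[[key]] / (ki * kj)
    out[bb[1], bb[2]] <- v
    out[bb[2], bb[1]] <- v
  }
  out
}

# rotated grid by explicit double loop over source pairs
brute_rotate <- function(values, D) {
  n <- nrow(values)
  grid <- matrix(NA_real_, D + 1, 2 * n - 1)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    if (j >= i && (j - i) <= D)
      grid[j - i + 1, i + j + 1] <- values[i + 1, j + 1]
  }
  grid
}

# per-base-pair accumulation of a track's value and coverage sums
bp_profile <- function(track, region) {
  width <- region$end - region$start
  vsum <- numeric(width)
  cov <- numeric(width)
  for (r in seq_len(nrow(track))) {
    s <- max(track$start[r], region$start)
    e <- min(track$end[r], region$end)
    if (s >= e) next
    idx <- (s - region$start + 1):(e - region$start)
    vsum[idx] <- vsum[idx] + track$value[r]
    cov[idx] <- cov[idx] + 1
  }
  list(vsum = vsum, cov = cov)
}

brute_bin_means <- function(track, region, resolution) {
  prof <- bp_profile(track, region)
  nb <- ceiling((region$end - region$start) / resolution)
  vapply(seq_len(nb), function(b) {
    lo <- (b - 1) * resolution + 1
    hi <- min(b * resolution, region$end - region$start)
    v <- sum(prof$vsum[lo:hi]); cc <- sum(prof$cov[lo:hi])
    if (cc > 0) v / cc else NA_real_
  }, 1)
}

brute_interval_mean <- function(track, s, e) {
  region <- genomic_region(track$chrom[1], min(s, track$start),
                           max(e, track$end))
  prof <- bp_profile(track, region)
  idx <- (s - region$start + 1):(e - region$start)
  if (sum(prof$cov[idx]) == 0) return(NA_real_)
  sum(prof$vsum[idx]) / sum(prof$cov[idx])
}

# random non-overlapping bedGraph-style track inside [0, width)
random_track <- function(width, max_intervals = 12, chrom = "chrT") {
  n <- sample.int(max_intervals, 1)
  cuts <- sort(sample(0:width, 2 * n))
  starts <- cuts[seq(1, 2 * n, 2)]
  ends <- cuts[seq(2, 2 * n, 2)]
  keep <- starts < ends
  if (!any(keep)) return(random_track(width, max_intervals, chrom))
  histogram_track(chrom, starts[keep], ends[keep],
                  round(stats::runif(sum(keep), -5, 10), 3))
}

random_symmetric_matrix <- function(n) {
  m <- matrix(stats::runif(n * n, 0, 100), n)
  (m + t(m)) / 2
}

small_interaction_matrix <- function(n = 8, resolution = 1000,
                                     chrom = "chrT") {
  interaction_matrix(genomic_region(chrom, 0, n * resolution), resolution,
                     random_symmetric_matrix(n))
}
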