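#' Specification of a synthetic TAD-structured contact matrix
#'
#' Describes the generative model used for test matrices: expected contact
#' between bins `i` and `j` decays as a power law of genomic distance,
#' `base * (1 + |i - j|)^(-decay_exponent)`, multiplied by an enrichment
#' factor when both bins fall inside the same TAD block, with
#' multiplicative lognormal noise (`sd` on the log scale).  This mimics
#' the two dominant features of real intrachromosomal Hi-C maps: the
#' distance-decay diagonal and block-enriched domains.
#'
#' @param n_bins Number of bins along the chromosome segment.
#' @param resolution Bin size in base pairs (default 25 kb, the working
#'   resolution of the balanced matrices the package targets).
#' @param tads Data.frame with `start_bin`, `end_bin` (0-based, half-open,
#'   within `[0, n_bins)`) and `factor` (> 1) columns, or NULL.
#' @param decay_exponent Power-law exponent (> 0); ~1 is typical of
#'   mammalian Hi-C at the sub-megabase scale.
#' @param noise_sd Standard deviation of the lognormal noise on the log
#'   scale; 0 gives the exact closed form.
#' @param base Expected diagonal intensity; the default keeps cell values
#'   in a realistic 0-1000 count range.
#' @param chrom,origin Chromosome name and start coordinate of the segment.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 120, resolution = 25000, tads = NULL,
                           decay_exponent = 1, noise_sd = 0.2, base = 1000,
                           chrom = "chrS", origin = 0, seed = 1) {
  if (!is.null(tads)) {
    stopifnot(all(c("start_bin", "end_bin", "factor") %in% names(tads)))
    if (any(tads$start_bin < 0 | tads$end_bin > n_bins |
            tads$start_bin >= tads$end_bin))
      stop("TAD spans must satisfy 0 <= start_bin < end_bin <= n_bins")
    if (any(tads$factor <= 1)) stop("TAD enrichment factors must exceed 1")
  }
  stopifnot(n_bins >= 1, resolution > 0, decay_exponent > 0, noise_sd >= 0,
            base > 0)
  structure(list(n_bins = as.integer(n_bins),
                 resolution = as.integer(resolution),
                 tads = tads, decay_exponent = decay_exponent,
                 noise_sd = noise_sd, base = base, chrom = chrom,
                 origin = origin, seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic TAD-structured interaction matrix
#'
#' Draws a symmetric contact matrix from the model described in
#' [synthetic_spec()].  At `noise_sd = 0` the output equals the closed
#' form exactly.  Noise is drawn for the upper triangle and mirrored, so
#' the matrix is exactly symmetric.
#'
#' @param spec A [synthetic_spec()].
#' @return An [interaction_matrix()] with attribute `"truth"` recording
#'   the spec (planted TADs included).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- spec$base * (1 + d)^(-spec$decay_exponent)
  if (!is.null(spec$tads)) {
    for (k in seq_len(nrow(spec$tads))) {
      idx <- (spec$tads$start_bin[k] + 1L):spec$tads$end_bin[k]
      expected[idx, idx] <- expected[idx, idx] * spec$tads$factor[k]
    }
  }
  values <- expected
  if (spec$noise_sd > 0) {
    values <- with_seed(spec$seed, {
      noise <- matrix(0, n, n)
      up <- upper.tri(noise, diag = TRUE)
      noise[up] <- stats::rnorm(sum(up), 0, spec$noise_sd)
      noise <- noise + t(noise * upper.tri(noise))   # mirror strict upper
      expected * exp(noise)
    })
  }
  region <- genomic_region(spec$chrom, spec$origin,
                           spec$origin + n * spec$resolution)
  out <- interaction_matrix(region, spec$resolution, values, "synthetic")
  attr(out, "truth") <- spec
  out
}

#' Emit a matrix as sparse triplet + normalization-vector files
#'
#' Writes the upper triangle of an interaction matrix in the 3-column
#' sparse dialect together with a per-bin balancing-score file, such that
#' [normalize_contacts()] on the two files reproduces the matrix.  The
#' raw counts written are `value * KR(i) * KR(j)`.
#'
#' @param matrix An [interaction_matrix()].
#' @param contacts_path,norm_path Output paths.
#' @param kr Per-bin balancing scores (recycled); default all 1.
#' @return Invisibly, a list with the two paths.
#' @export
write_sparse_fixture <- function(matrix, contacts_path, norm_path, kr = 1) {
  n <- nrow(matrix$values)
  kr <- rep_len(kr, n)
  idx <- which(upper.tri(matrix$values, diag = TRUE) &
               is.finite(matrix$values) & matrix$values > 0, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  raw <- matrix$values[idx] * kr[i] * kr[j]
  pos_i <- matrix$region$start + (i - 1) * matrix$resolution
  pos_j <- matrix$region$start + (j - 1) * matrix$resolution
  writeLines(sprintf("%d\t%d\t%s", as.integer(pos_i), as.integer(pos_j),
                     format(raw, digits = 17, trim = TRUE,
                            scientific = FALSE)), contacts_path)
  # scores indexed from chromosome position 0
  lead <- matrix$region$start %/% matrix$resolution
  writeLines(c(rep("NaN", lead),
               format(kr, digits = 17, trim = TRUE, scientific = FALSE)),
             norm_path)
  invisible(list(contacts = contacts_path, norm = norm_path))
}

#' Generate a two-state replication-timing signal
#'
#' Emulates a Repli-Seq style track: the region is partitioned into
#' alternating "early" and "late" replication blocks with geometrically
#' distributed lengths (mean `block_length_mean`, quantized to `step`),
#' and each block is tiled with fixed-width bedGraph intervals at the
#' block's level plus small Gaussian noise.
#'
#' @param region [genomic_region()] to cover.
#' @param block_length_mean Mean block length in base pairs.
#' @param early_level,late_level Signal levels of the two states (early
#'   high, late low, as in replication-timing data).
#' @param noise_sd Gaussian noise added per emitted interval.
#' @param step Quantum of block lengths and width of emitted intervals.
#' @param seed Integer seed.
#' @return A `histogram_track` with attribute `"blocks"`: a data.frame of
#'   `start`, `end`, `state` ("early"/"late") giving the planted truth.
#' @export
generate_replication_signal <- function(region, block_length_mean = 500e3,
                                        early_level = 60, late_level = 20,
                                        noise_sd = 2, step = 25e3,
                                        seed = 1) {
  stopifnot(inherits(region, "genomic_region"), block_length_mean >= step)
  with_seed(seed, {
    width <- region_width(region)
    # block length = step * (1 + Geom), mean = block_length_mean
    p <- min(1, step / block_length_mean)
    starts <- ends <- numeric(0); states <- character(0)
    pos <- region$start
    state <- if (stats::runif(1) < 0.5) "early" else "late"
    while (pos < region$end) {
      len <- step * (1 + stats::rgeom(1, p))
      e <- min(pos + len, region$end)
      starts <- c(starts, pos); ends <- c(ends, e)
      states <- c(states, state)
      pos <- e
      state <- if (state == "early") "late" else "early"
    }
    blocks <- data.frame(start = starts, end = ends, state = states)
    # tile each block with step-sized intervals
    iv_start <- iv_val <- numeric(0)
    for (k in seq_len(nrow(blocks))) {
      s <- seq(blocks$start[k], blocks$end[k] - 1, by = step)
      lev <- if (blocks$state[k] == "early") early_level else late_level
      iv_start <- c(iv_start, s)
      iv_val <- c(iv_val, lev + stats::rnorm(length(s), 0, noise_sd))
    }
    iv_end <- pmin(iv_start + step, region$end)
    track <- histogram_track(region$chrom, iv_start, iv_end, iv_val,
                             "replication timing (synthetic)")
    attr(track, "blocks") <- blocks
    track
  })
}

#' Generate interaction anchor pairs biased into early blocks
#'
#' Emulates cohesin ChIA-PET interactions concentrated in early-replicating
#' chromatin: with probability `bias` both anchors of a pair are placed
#' uniformly inside (distinct) early blocks; otherwise both are placed
#' uniformly anywhere in the region.  Anchor pairs always span at least
#' one block boundary.
#'
#' @param replication_track Output of [generate_replication_signal()]
#'   (its `"blocks"` attribute supplies the early-block truth).
#' @param n_pairs Number of anchor pairs.
#' @param bias Probability in `[0, 1]` that a pair targets early blocks.
#' @param anchor_width Width of each anchor interval in base pairs.
#' @param seed Integer seed.
#' @return An `arc_track` with attribute `"planted_early"`: logical vector
#'   marking the biased pairs.
#' @export
generate_anchors <- function(replication_track, n_pairs = 200, bias = 0.9,
                             anchor_width = 10e3, seed = 1) {
  blocks <- attr(replication_track, "blocks")
  if (is.null(blocks)) stop("replication track carries no block truth")
  stopifnot(bias >= 0, bias <= 1, n_pairs >= 1)
  chrom <- replication_track$chrom[1]
  region_start <- min(blocks$start); region_end <- max(blocks$end)
  early <- blocks[blocks$state == "early" &
                  blocks$end - blocks$start >= anchor_width, , drop = FALSE]
  if (bias > 0 && nrow(early) < 2L)
    stop("need at least two early blocks wide enough for an anchor")
  with_seed(seed, {
    planted <- stats::runif(n_pairs) < bias
    draw_in <- function(s, e) s + floor(stats::runif(1) * (e - s - anchor_width + 1))
    s1 <- s2 <- numeric(n_pairs)
    for (k in seq_len(n_pairs)) {
      if (planted[k]) {
        bl <- sample.int(nrow(early), 2)    # two distinct early blocks
        s1[k] <- draw_in(early$start[bl[1]], early$end[bl[1]])
        s2[k] <- draw_in(early$start[bl[2]], early$end[bl[2]])
      } else {
        repeat {                            # uniform, but spanning blocks
          a <- draw_in(region_start, region_end)
          b <- draw_in(region_start, region_end)
          blk <- findInterval(c(a, b), blocks$start)
          if (blk[1] != blk[2]) { s1[k] <- a; s2[k] <- b; break }
        }
      }
    }
    out <- arc_track(chrom, s1, s1 + anchor_width, s2, s2 + anchor_width,
                     name = "anchors (synthetic)")
    attr(out, "planted_early") <- planted
    out
  })
}

#' Generate a chromatin-state tile partition
#'
#' Partitions the region into consecutive tiles with exponential-ish
#' lengths and assigns each a state label drawn from `probs`, mimicking a
#' segmentation such as ChromHMM output.
#'
#' @param region [genomic_region()] to partition.
#' @param states Character vector of state labels.
#' @param probs Label probabilities (recycled/normalized); default uniform.
#' @param mean_tile Mean tile length in base pairs.
#' @param step Length quantum.
#' @param seed Integer seed.
#' @return A `tile_track` that tiles `region` exactly, without overlaps.
#' @export
generate_state_tiles <- function(region, states = c("Enh", "Txn", "Het",
                                                    "Prom", "Quies"),
                                 probs = NULL, mean_tile = 100e3,
                                 step = 5e3, seed = 1) {
  stopifnot(inherits(region, "genomic_region"), length(states) >= 1)
  if (is.null(probs)) probs <- rep(1, length(states))
  probs <- probs / sum(probs)
  with_seed(seed, {
    p <- min(1, step / mean_tile)
    starts <- ends <- numeric(0); labels <- character(0)
    pos <- region$start
    while (pos < region$end) {
      len <- step * (1 + stats::rgeom(1, p))
      e <- min(pos + len, region$end)
      starts <- c(starts, pos); ends <- c(ends, e)
      labels <- c(labels, sample(states, 1, prob = probs))
      pos <- e
    }
    tile_track(region$chrom, starts, ends, labels,
               name = "chromatin states (synthetic)")
  })
}

#' Write a complete synthetic fixture set
#'
#' Emits, under `outdir`, every file dialect the readers consume — dense
#' matrix, sparse contacts + balancing vector, bedGraph signal, state
#' tiles, TAD domains, anchor arcs — plus a `truth.json` sidecar recording
#' the planted structure, for recovery tests and CLI runs.
#'
#' @param outdir Output directory (created if needed).
#' @param spec A [synthetic_spec()]; its seed drives every generator.
#' @param n_pairs,bias Passed to [generate_anchors()].
#' @param block_length_mean Mean replication-block length; the default
#'   fits about 20 blocks into the simulated segment so that even small
#'   test regions carry several early/late alternations.
#' @return Invisibly, a named list of the paths written plus the truth.
#' @export
simulate_fixtures <- function(outdir, spec = synthetic_spec(),
                              n_pairs = 50, bias = 0.9,
                              block_length_mean = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mat <- generate_matrix(spec)
  region <- mat$region
  paths <- list(
    dense = file.path(outdir, "matrix_dense.txt"),
    contacts = file.path(outdir, "contacts_sparse.txt"),
    norm = file.path(outdir, "kr_scores.txt"),
    signal = file.path(outdir, "replication.bedGraph"),
    tiles = file.path(outdir, "states.bed"),
    domains = file.path(outdir, "domains.bed"),
    arcs = file.path(outdir, "anchors.txt"),
    truth = file.path(outdir, "truth.json"))
  write_dense_matrix(mat, paths$dense)
  kr <- with_seed(spec$seed, stats::runif(spec$n_bins, 0.5, 2))
  write_sparse_fixture(mat, paths$contacts, paths$norm, kr)
  if (is.null(block_length_mean))
    block_length_mean <- max(2 * spec$resolution, region_width(region) / 20)
  signal <- generate_replication_signal(
    region, block_length_mean = block_length_mean, step = spec$resolution,
    seed = spec$seed)
  write_bedgraph(signal, paths$signal, header = TRUE)
  tiles <- generate_state_tiles(region, seed = spec$seed)
  write_tiles(tiles, paths$tiles)
  if (!is.null(spec$tads)) {
    dom <- domain_track(region$chrom,
                        region$start + spec$tads$start_bin * spec$resolution,
                        region$start + spec$tads$end_bin * spec$resolution,
                        "planted TADs")
  } else dom <- domain_track(character(0), numeric(0), numeric(0))
  write_domains(dom, paths$domains)
  arcs <- generate_anchors(signal, n_pairs = n_pairs, bias = bias,
                           seed = spec$seed)
  write_arcs(arcs, paths$arcs)
  truth <- list(
    region = list(chrom = region$chrom, start = region$start,
                  end = region$end),
    resolution = spec$resolution, n_bins = spec$n_bins, seed = spec$seed,
    decay_exponent = spec$decay_exponent, noise_sd = spec$noise_sd,
    base = spec$base,
    tads = if (is.null(spec$tads)) list() else spec$tads,
    blocks = attr(signal, "blocks"),
    n_pairs = n_pairs, bias = bias,
    n_planted_early = sum(attr(arcs, "planted_early")),
    total_raw_count = sum(as.numeric(
      read_sparse_contacts(paths$contacts)$count)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, list(truth_data = truth)))
}
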