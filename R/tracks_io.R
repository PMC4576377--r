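#' Track constructors
#'
#' Lightweight S3 containers for linear genomic annotations, all using
#' 0-based half-open coordinates on a single chromosome:
#'
#' * `histogram_track`: intervals carrying a continuous value (bedGraph).
#' * `tile_track`: labeled, optionally colored intervals (BED-like), e.g.
#'   chromatin-state calls.
#' * `domain_track`: plain intervals drawn as triangles (TADs, contact
#'   domains), one color per set.
#' * `arc_track`: interval pairs with an optional score, drawn as arcs
#'   (e.g. ChIA-PET interactions); anchors are stored canonically ordered
#'   left to right.
#'
#' @param chrom,start,end,value,label,color,start1,end1,start2,end2,score
#'   Parallel vectors of interval fields.
#' @param name Track display name.
#' @return A data.frame with the corresponding subclass.
#' @name tracks
NULL

check_intervals <- function(start, end, what = "interval") {
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s %d has start (%s) >= end (%s)", what, bad[1],
                 format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)))
  invisible(TRUE)
}

#' @rdname tracks
#' @export
histogram_track <- function(chrom, start, end, value, name = "") {
  check_intervals(start, end)
  if (length(unique(chrom)) > 1L)
    stop("a histogram track must stay on one chromosome")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), value = as.numeric(value))
  attr(out, "name") <- name
  class(out) <- c("histogram_track", "data.frame")
  out
}

#' @rdname tracks
#' @export
tile_track <- function(chrom, start, end, label = "", color = NA_character_,
                       name = "") {
  check_intervals(start, end, "tile")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    label = rep_len(as.character(label), length(start)),
                    color = rep_len(as.character(color), length(start)))
  attr(out, "name") <- name
  class(out) <- c("tile_track", "data.frame")
  out
}

#' @rdname tracks
#' @export
domain_track <- function(chrom, start, end, name = "", color = "khaki3") {
  check_intervals(start, end, "domain")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end))
  attr(out, "name") <- name
  attr(out, "color") <- validate_color(color)
  class(out) <- c("domain_track", "data.frame")
  out
}

#' @rdname tracks
#' @export
arc_track <- function(chrom, start1, end1, start2, end2, score = 1,
                      name = "") {
  check_intervals(start1, end1, "anchor A of pair")
  check_intervals(start2, end2, "anchor B of pair")
  # canonical ordering: left anchor first
  swap <- start2 < start1
  s1 <- ifelse(swap, start2, start1); e1 <- ifelse(swap, end2, end1)
  s2 <- ifelse(swap, start1, start2); e2 <- ifelse(swap, end1, end2)
  out <- data.frame(chrom = as.character(chrom),
                    start1 = as.numeric(s1), end1 = as.numeric(e1),
                    start2 = as.numeric(s2), end2 = as.numeric(e2),
                    score = rep_len(as.numeric(score), length(s1)))
  attr(out, "name") <- name
  class(out) <- c("arc_track", "data.frame")
  out
}

parse_bed_like <- function(path) {
  dat <- read_data_lines(path)
  keep <- !grepl("^(track|browser|#)", dat$lines)
  list(toks = lapply(dat$lines[keep], split_ws), lineno = dat$lineno[keep],
       n_header = sum(!keep))
}

#' Read a bedGraph file
#'
#' 4-column text `chrom start end value`, 0-based half-open.  `track`,
#' `browser` and `#` header lines are skipped; blank lines and trailing
#' whitespace are ignored.
#'
#' @param path Path to the bedGraph file.
#' @param name Track display name (defaults to the file name).
#' @return A `histogram_track`.
#' @export
read_bedgraph <- function(path, name = basename(path)) {
  p <- parse_bed_like(path)
  n <- length(p$toks)
  if (n == 0L)
    return(histogram_track(character(0), numeric(0), numeric(0), numeric(0),
                           name))
  for (k in seq_len(n)) {
    t <- p$toks[[k]]
    if (length(t) < 4L)
      stop(sprintf("line %d of %s: bedGraph needs 4 columns, found %d",
                   p$lineno[k], path, length(t)))
    if (is.na(suppressWarnings(as.numeric(t[4]))))
      stop(sprintf("line %d of %s: non-numeric value '%s'",
                   p$lineno[k], path, t[4]))
  }
  m <- do.call(rbind, lapply(p$toks, `[`, 1:4))
  histogram_track(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]),
                  as.numeric(m[, 4]), name)
}

#' Write a bedGraph file
#' @param track A `histogram_track`.
#' @param path Output path.
#' @param header Write a `track type=bedGraph` header line?
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, header = FALSE) {
  con <- file(path, "w"); on.exit(close(con))
  if (header) writeLines("track type=bedGraph", con)
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                     as.integer(track$end),
                     format(track$value, digits = 15, trim = TRUE,
                            scientific = FALSE)), con)
  invisible(path)
}

read_bed3_plus <- function(path) {
  p <- parse_bed_like(path)
  n <- length(p$toks)
  if (n == 0L) return(NULL)
  for (k in seq_len(n)) {
    t <- p$toks[[k]]
    if (length(t) < 3L)
      stop(sprintf("line %d of %s: need at least chrom/start/end",
                   p$lineno[k], path))
    se <- suppressWarnings(as.numeric(t[2:3]))
    if (any(is.na(se)))
      stop(sprintf("line %d of %s: non-numeric coordinate", p$lineno[k], path))
    if (se[1] >= se[2])
      stop(sprintf("line %d of %s: start (%s) >= end (%s)",
                   p$lineno[k], path, t[2], t[3]))
  }
  list(chrom = vapply(p$toks, `[`, "", 1),
       start = as.numeric(vapply(p$toks, `[`, "", 2)),
       end = as.numeric(vapply(p$toks, `[`, "", 3)),
       col4 = vapply(p$toks, function(t) if (length(t) >= 4) t[4] else "", ""),
       col5 = vapply(p$toks, function(t) if (length(t) >= 5) t[5] else "", ""))
}

#' Read a BED-like tile file
#'
#' `chrom start end [label] [color]`; a missing label becomes the empty
#' string and a missing or invalid color falls back to the track default.
#'
#' @inheritParams read_bedgraph
#' @return A `tile_track`.
#' @export
read_tiles <- function(path, name = basename(path)) {
  b <- read_bed3_plus(path)
  if (is.null(b))
    return(tile_track(character(0), numeric(0), numeric(0), name = name))
  color <- vapply(b$col5, function(cl)
    if (nzchar(cl)) validate_color(cl, NA_character_) else NA_character_, "")
  tile_track(b$chrom, b$start, b$end, b$col4, color, name)
}

#' Read a BED-like domain file
#'
#' `chrom start end` (extra columns ignored); one color per set, supplied
#' by the caller.
#'
#' @inheritParams read_bedgraph
#' @param color Display color for this domain set.
#' @return A `domain_track`.
#' @export
read_domains <- function(path, name = basename(path), color = "khaki3") {
  b <- read_bed3_plus(path)
  if (is.null(b))
    return(domain_track(character(0), numeric(0), numeric(0), name, color))
  domain_track(b$chrom, b$start, b$end, name, color)
}

#' Read a paired-loci arc file
#'
#' `chrom start1 end1 start2 end2 [score]`, both anchors on the same
#' chromosome.  Anchors are canonically ordered left-to-right; a missing
#' score defaults to 1.
#'
#' @inheritParams read_bedgraph
#' @return An `arc_track`.
#' @export
read_arcs <- function(path, name = basename(path)) {
  p <- parse_bed_like(path)
  n <- length(p$toks)
  if (n == 0L)
    return(arc_track(character(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), name = name))
  for (k in seq_len(n)) {
    t <- p$toks[[k]]
    if (length(t) < 5L)
      stop(sprintf("line %d of %s: need chrom start1 end1 start2 end2 [score]",
                   p$lineno[k], path))
    if (length(t) >= 7L && !is_numeric_token(t[2]))
      stop(sprintf("line %d of %s: two-chromosome arc records are not supported",
                   p$lineno[k], path))
    if (any(is.na(suppressWarnings(as.numeric(t[2:5])))))
      stop(sprintf("line %d of %s: non-numeric coordinate", p$lineno[k], path))
  }
  score <- vapply(p$toks, function(t)
    if (length(t) >= 6) as.numeric(t[6]) else 1, 1)
  g <- function(i) as.numeric(vapply(p$toks, `[`, "", i))
  arc_track(vapply(p$toks, `[`, "", 1), g(2), g(3), g(4), g(5), score, name)
}

#' Write arcs/tiles/domains
#' @param track The track to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arcs <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%s", track$chrom,
                     as.integer(track$start1), as.integer(track$end1),
                     as.integer(track$start2), as.integer(track$end2),
                     format(track$score, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' @rdname write_arcs
#' @export
write_tiles <- function(track, path) {
  lab <- ifelse(nzchar(track$label), track$label, ".")
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                     as.integer(track$end), lab), path)
  invisible(path)
}

#' @rdname write_arcs
#' @export
write_domains <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d", track$chrom, as.integer(track$start),
                     as.integer(track$end)), path)
  invisible(path)
}

# ---- piecewise-constant signal machinery ---------------------------------
#
# A histogram track defines, at every base pair x, V(x) = sum of values of
# intervals covering x and C(x) = number of covering intervals.  The
# coverage-weighted mean of the track over any query span [s, e) is
#     integral of V over [s, e) / integral of C over [s, e)
#   = sum over intervals of value * overlap_bp / sum of overlap_bp,
# which for the usual non-overlapping bedGraph is simply the mean of the
# interval values weighted by the number of covered base pairs.

flatten_track <- function(track) {
  if (nrow(track) == 0L)
    return(list(bp = numeric(0), v = numeric(0), c = numeric(0),
                iv = numeric(0), ic = numeric(0)))
  pos <- c(track$start, track$end)
  dv <- c(track$value, -track$value)
  dc <- c(rep(1, nrow(track)), rep(-1, nrow(track)))
  o <- order(pos)
  pos <- pos[o]; dv <- dv[o]; dc <- dc[o]
  bp <- unique(pos)
  v <- cumsum(rowsum(dv, match(pos, bp), reorder = FALSE))
  cc <- cumsum(rowsum(dc, match(pos, bp), reorder = FALSE))
  cc <- round(cc)                            # exact integer coverage
  seglen <- diff(bp)
  m <- length(bp) - 1L
  # cumulative integrals of V and C from bp[1] to each breakpoint
  iv <- c(0, cumsum(v[seq_len(m)] * seglen))
  ic <- c(0, cumsum(cc[seq_len(m)] * seglen))
  list(bp = bp, v = as.numeric(v), c = as.numeric(cc), iv = iv, ic = ic)
}

# integral of V (and C) from bp[1] to arbitrary positions x
flat_integrals <- function(flat, x) {
  if (length(flat$bp) == 0L)
    return(list(iv = rep(0, length(x)), ic = rep(0, length(x))))
  x <- pmin(pmax(x, flat$bp[1]), flat$bp[length(flat$bp)])
  k <- findInterval(x, flat$bp)
  dx <- x - flat$bp[k]
  last <- k == length(flat$bp)
  vstep <- ifelse(last, 0, flat$v[k])
  cstep <- ifelse(last, 0, flat$c[k])
  list(iv = flat$iv[k] + dx * vstep, ic = flat$ic[k] + dx * cstep)
}

# coverage-weighted mean of the track over each query span; NA if uncovered
flat_means <- function(flat, starts, ends) {
  a <- flat_integrals(flat, starts)
  b <- flat_integrals(flat, ends)
  num <- b$iv - a$iv
  den <- b$ic - a$ic
  ifelse(den > 0, num / den, NA_real_)
}

#' Aggregate a histogram track onto display bins
#'
#' Each bin's value is the coverage-weighted mean of the track over the
#' bin: `sum(value * overlap_bp) / sum(overlap_bp)` across intervals
#' overlapping the bin.  Bins with no coverage are `NA`.  With
#' `aggregator = "max"` the bin takes the maximum value among overlapping
#' intervals instead (useful for sharp peaks at coarse resolutions).
#'
#' @param track A `histogram_track`.
#' @param region [genomic_region()] to bin over.
#' @param resolution Bin size in base pairs.
#' @param aggregator `"mean"` (coverage-weighted, the default) or `"max"`.
#' @return An object of class `binned_signal`: list with `region`,
#'   `resolution` and numeric `values` (one per bin).
#' @export
bin_signal <- function(track, region, resolution,
                       aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(track, "histogram_track"), resolution > 0)
  nb <- n_bins(region, resolution)
  starts <- region$start + (seq_len(nb) - 1) * resolution
  ends <- pmin(starts + resolution, region$end)
  if (aggregator == "mean") {
    vals <- flat_means(flatten_track(track), starts, ends)
  } else {
    vals <- rep(NA_real_, nb)
    for (b in seq_len(nb)) {
      hit <- track$value[track$start < ends[b] & track$end > starts[b]]
      if (length(hit)) vals[b] <- max(hit)
    }
  }
  structure(list(region = region, resolution = as.integer(resolution),
                 values = vals, name = attr(track, "name")),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat(sprintf("<binned_signal> %s @ %s bp: %d bins (%d covered)\n",
              format(x$region), format(x$resolution, big.mark = ","),
              length(x$values), sum(!is.na(x$values))))
  invisible(x)
}
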