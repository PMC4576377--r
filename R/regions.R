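#' Genomic region
#'
#' Construct a genomic region: a chromosome name plus a 0-based, half-open
#' coordinate span `[start, end)`.  This is the universal addressing unit of
#' the package; all readers and renderers use the same convention, which
#' matches bedGraph/BED files.
#'
#' @param chrom Chromosome name, e.g. `"chr10"`.
#' @param start Start coordinate in base pairs (0-based, inclusive).
#' @param end End coordinate in base pairs (exclusive); must exceed `start`.
#' @return An object of class `genomic_region`: a list with elements
#'   `chrom`, `start` and `end`.
#' @examples
#' genomic_region("chr10", 0, 1e6)
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing numbers")
  if (start < 0) stop("start must be non-negative, got ", start)
  if (start >= end)
    stop("region start (", start, ") must be smaller than end (", end, ")")
  if (start != floor(start) || end != floor(end))
    stop("region coordinates must be whole base pairs")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

#' @export
format.genomic_region <- function(x, ...) {
  sprintf("%s:%d-%d", x$chrom, x$start, x$end)
}

region_width <- function(region) region$end - region$start

#' Number of bins covering a region
#'
#' `ceiling(width / resolution)`: the final bin may extend past `end` when
#' the width is not a multiple of the resolution.
#'
#' @param region A [genomic_region()].
#' @param resolution Bin size in base pairs.
#' @return Integer bin count.
#' @export
n_bins <- function(region, resolution) {
  stopifnot(resolution > 0)
  as.integer(ceiling(region_width(region) / resolution))
}

# bin index (0-based) of a genomic position relative to region start
bin_index <- function(pos, region, resolution) {
  floor((pos - region$start) / resolution)
}

region_contains <- function(outer, inner) {
  identical(outer$chrom, inner$chrom) &&
    inner$start >= outer$start && inner$end <= outer$end
}

#' Snap a region outward onto a resolution grid
#'
#' Start is rounded down and end rounded up to the nearest multiple of
#' `resolution` (measured from position 0), so that no requested base pair
#' is dropped.  A warning is emitted when snapping changes the region.
#'
#' @param region A [genomic_region()].
#' @param resolution Grid size in base pairs.
#' @return A snapped `genomic_region`.
#' @export
snap_region <- function(region, resolution) {
  s <- floor(region$start / resolution) * resolution
  e <- ceiling(region$end / resolution) * resolution
  if (s != region$start || e != region$end) {
    warning(sprintf(
      "region %s snapped outward to %s:%d-%d to align with %d-bp grid",
      format(region), region$chrom, s, e, as.integer(resolution)))
  }
  genomic_region(region$chrom, s, e)
}
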