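#' Rotated half-matrix representation
#'
#' A symmetric interaction matrix re-indexed by (distance from the
#' diagonal, midpoint), the lossless form behind the 45-degree rotated
#' triangle display.  For a source pair of bins `i <= j` (0-based) the
#' cell lands at row `d = j - i` and column `m = i + j` of a
#' `(D + 1) x (2n - 1)` grid, `D = floor(max_distance / resolution)`.
#' Grid cells that correspond to no source pair — columns of the wrong
#' parity, or beyond the triangle's sloping edges — are `NA`.  Row `d = 0`
#' is the source diagonal.
#'
#' @param matrix An [interaction_matrix()]; must be symmetric (asymmetry
#'   beyond a 1e-8 relative tolerance is averaged out with a warning by
#'   the constructor).
#' @param max_distance Distance cap in base pairs: pairs farther apart
#'   than this are dropped.  Default 8 Mb, the customary ceiling for a
#'   TAD-scale triangle plot.  Must be at least one bin.
#' @return An object of class `rotated_matrix`: list with `region`,
#'   `resolution`, `max_distance`, and the `values` grid.
#' @examples
#' m <- interaction_matrix(genomic_region("chr1", 0, 75e3), 25e3,
#'                         matrix(c(5, 1, 0, 1, 5, 2, 0, 2, 5), 3))
#' rotate_half_matrix(m, 50e3)$values
#' @export
rotate_half_matrix <- function(matrix, max_distance = 8e6) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  res <- matrix$resolution
  if (max_distance < res)
    stop("max_distance (", max_distance,
         ") must be at least one bin (resolution ", res, ")")
  n <- nrow(matrix$values)
  D <- as.integer(max_distance %/% res)     # rows beyond n-1 stay all-NA
  grid <- matrix(NA_real_, nrow = D + 1L, ncol = 2L * n - 1L)
  for (d in 0:min(D, n - 1L)) {
    i <- seq_len(n - d)                     # 1-based source rows
    # column m = (i-1) + (i-1+d) on the 0-based midpoint grid
    grid[d + 1L, 2L * (i - 1L) + d + 1L] <- matrix$values[cbind(i, i + d)]
  }
  structure(list(region = matrix$region, resolution = res,
                 max_distance = as.numeric(max_distance),
                 label = matrix$label, values = grid),
            class = "rotated_matrix")
}

#' @export
print.rotated_matrix <- function(x, ...) {
  cat(sprintf(
    "<rotated_matrix> %s @ %s bp: %d distance rows x %d midpoint columns (cap %s bp)\n",
    format(x$region), format(x$resolution, big.mark = ","),
    nrow(x$values), ncol(x$values),
    format(x$max_distance, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Reconstruct the source band from a rotated half matrix
#'
#' Inverse of [rotate_half_matrix()]: rebuilds the band `|i - j| <= D` of
#' the source matrix exactly; cells outside the band are `NA`.
#'
#' @param rot A `rotated_matrix`.
#' @return An [interaction_matrix()] whose finite cells form the band.
#' @export
unrotate <- function(rot) {
  stopifnot(inherits(rot, "rotated_matrix"))
  n <- (ncol(rot$values) + 1L) %/% 2L
  D <- min(nrow(rot$values) - 1L, n - 1L)
  values <- matrix(NA_real_, n, n)
  for (d in 0:D) {
    i <- seq_len(n - d)
    v <- rot$values[d + 1L, 2L * (i - 1L) + d + 1L]
    values[cbind(i, i + d)] <- v
    values[cbind(i + d, i)] <- v
  }
  interaction_matrix(rot$region, rot$resolution, values, rot$label)
}

#' Map a genomic position to a panel axis coordinate
#'
#' The shared-x-axis contract across panel kinds: square heatmap panels use
#' fractional bin units (bin `i` spans axis `[i, i + 1)`) and rotated
#' triangle panels use midpoint-grid units, where source bin `i` sits at
#' column `2 i` — exactly twice the heatmap coordinate, so the two panel
#' kinds always refer to the same base pair after a factor-of-two scaling.
#'
#' @param pos Genomic position in base pairs; must lie inside `region`
#'   (both ends inclusive).
#' @param region [genomic_region()] shown on the axis.
#' @param resolution Bin size in base pairs.
#' @param panel `"heatmap"` (default) or `"triangle"`.
#' @return The (fractional) axis coordinate: 0 at `region$start`.
#' @export
genomic_to_axis <- function(pos, region, resolution,
                            panel = c("heatmap", "triangle")) {
  panel <- match.arg(panel)
  if (any(pos < region$start | pos > region$end))
    stop("position ", pos[which(pos < region$start | pos > region$end)[1]],
         " outside region ", format(region))
  x <- (pos - region$start) / resolution
  if (panel == "triangle") 2 * x else x
}
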