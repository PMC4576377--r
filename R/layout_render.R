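#' Panel specification
#'
#' One panel of a figure column: a contact-matrix view or a linear track.
#'
#' @param kind One of `"heatmap"`, `"triangle"`, `"histogram"`, `"tiles"`,
#'   `"arcs"`, `"domains"`.
#' @param data The payload, whose class must match `kind`: an
#'   [interaction_matrix()] for matrix kinds, a `histogram_track`,
#'   `tile_track`, `arc_track`, or (a list of) `domain_track`.
#' @param label Panel label; defaults to the payload's track name.
#' @param max_distance Triangle panels only: distance cap in bp
#'   (default 8e6; see [rotate_half_matrix()]).
#' @param zlim Matrix panels: explicit color range, overriding the default
#'   saturation at the 98th percentile of in-window finite values.
#' @param ylim Histogram panels: explicit y range.
#' @param color Fill color for histogram bars.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(kind = c("heatmap", "triangle", "histogram", "tiles",
                                "arcs", "domains"),
                       data, label = NULL, max_distance = 8e6, zlim = NULL,
                       ylim = NULL, color = "grey30") {
  kind <- match.arg(kind)
  ok <- switch(kind,
    heatmap = , triangle = inherits(data, "interaction_matrix"),
    histogram = inherits(data, "histogram_track"),
    tiles = inherits(data, "tile_track"),
    arcs = inherits(data, "arc_track"),
    domains = inherits(data, "domain_track") ||
      (is.list(data) && all(vapply(data, inherits, TRUE, "domain_track"))))
  if (!ok) stop("panel payload class does not match kind '", kind, "'")
  if (kind == "domains" && inherits(data, "domain_track")) data <- list(data)
  if (is.null(label))
    label <- if (kind %in% c("heatmap", "triangle")) data$label
             else if (kind == "domains") ""
             else attr(data, "name") %||% ""
  structure(list(kind = kind, data = data, label = label,
                 max_distance = max_distance, zlim = zlim, ylim = ylim,
                 color = validate_color(color)),
            class = "panel_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Figure specification
#'
#' Declarative description of a whole figure: an ordered set of
#' experimental conditions, each a column of stacked panels sharing one
#' genomic x-axis, plus optional highlighted regions (translucent vertical
#' spans crossing every panel) and loop annotations (markers on matrix
#' panels).
#'
#' @param window [genomic_region()] shown on the common x-axis.
#' @param conditions Named list: condition label -> list of
#'   [panel_spec()]s (at least one condition with at least one panel).
#' @param highlights List of [genomic_region()]s to shade.
#' @param loops An `arc_track` (or data.frame with `start1/end1/start2/end2`)
#'   of loci pairs to mark on matrix panels.
#' @param output Output image path; format chosen by extension (`.png`,
#'   `.pdf`, `.svg`).  `NULL` renders to a discarded device, producing the
#'   layout report only.
#' @param shared_color_scale If `TRUE`, all matrix panels across all
#'   conditions share one color range (the global range of in-window
#'   finite values after saturation).
#' @return An object of class `figure_spec`.
#' @export
figure_spec <- function(window, conditions, highlights = list(),
                        loops = NULL, output = NULL,
                        shared_color_scale = FALSE) {
  stopifnot(inherits(window, "genomic_region"))
  if (length(conditions) < 1L) stop("need at least one condition")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    names(conditions) <- paste("condition", seq_along(conditions))
  for (lab in names(conditions)) {
    panels <- conditions[[lab]]
    if (inherits(panels, "panel_spec")) conditions[[lab]] <- panels <- list(panels)
    if (length(panels) < 1L)
      stop("condition '", lab, "' has no panels")
    for (p in panels) {
      if (!inherits(p, "panel_spec")) stop("conditions must hold panel_spec objects")
      check_panel_coverage(p, window)
    }
  }
  if (inherits(highlights, "genomic_region")) highlights <- list(highlights)
  for (h in highlights) stopifnot(inherits(h, "genomic_region"))
  structure(list(window = window, conditions = conditions,
                 highlights = highlights, loops = loops, output = output,
                 shared_color_scale = isTRUE(shared_color_scale)),
            class = "figure_spec")
}

check_panel_coverage <- function(p, window) {
  if (p$kind %in% c("heatmap", "triangle")) {
    if (!region_contains(p$data$region, window))
      stop(sprintf("matrix panel '%s' (%s) does not cover window %s",
                   p$label, format(p$data$region), format(window)))
  } else {
    tracks <- if (p$kind == "domains") p$data else list(p$data)
    for (tr in tracks) {
      if (nrow(tr) && !all(tr$chrom == window$chrom))
        stop(sprintf("track '%s' is on %s, window is on %s",
                     attr(tr, "name") %||% p$label, tr$chrom[1], window$chrom))
    }
  }
  invisible(TRUE)
}

# ---- geometry helpers (the testable rendering contract) ------------------

#' Domain-panel geometry
#'
#' Computes (and optionally draws) the triangle geometry for one or more
#' domain sets: each domain becomes an isoceles triangle with base
#' `[start, end]` on the x-axis, apex at `x = (start + end) / 2`, and
#' height proportional to the domain width (`(end - start) / 2`, the
#' 45-degree slope convention).  Multiple sets are overlaid, one color per
#' set.
#'
#' @param domain_sets List of `domain_track`s (or a single one).
#' @param window [genomic_region()]; domains not overlapping it are
#'   dropped from the geometry.
#' @param draw Draw onto the current device?
#' @return A data.frame with `set`, `color`, `start`, `end`, `apex_x`,
#'   `height`, one row per in-window domain.
#' @export
render_domains_panel <- function(domain_sets, window, draw = FALSE) {
  if (inherits(domain_sets, "domain_track")) domain_sets <- list(domain_sets)
  if (length(domain_sets) < 1L) stop("need at least one domain set")
  geom <- do.call(rbind, lapply(seq_along(domain_sets), function(k) {
    tr <- domain_sets[[k]]
    keep <- tr$start < window$end & tr$end > window$start
    d <- tr[keep, , drop = FALSE]
    if (!nrow(d))
      return(NULL)
    data.frame(set = attr(tr, "name") %||% paste0("set", k),
               color = attr(tr, "color") %||% "khaki3",
               start = d$start, end = d$end,
               apex_x = (d$start + d$end) / 2,
               height = (d$end - d$start) / 2)
  }))
  if (is.null(geom))
    geom <- data.frame(set = character(0), color = character(0),
                       start = numeric(0), end = numeric(0),
                       apex_x = numeric(0), height = numeric(0))
  if (draw && nrow(geom)) {
    for (r in seq_len(nrow(geom)))
      graphics::polygon(c(geom$start[r], geom$apex_x[r], geom$end[r]),
                        c(0, geom$height[r], 0), border = geom$color[r],
                        col = NA, lwd = 1.5)
  }
  geom
}

#' Arc-panel geometry
#'
#' Computes (and optionally draws) arc geometry: each pair is a curve
#' between the midpoints of its two anchors with height proportional to
#' the midpoint span; the optional score maps linearly to line width.
#' Pairs whose midpoints coincide are degenerate and skipped with a
#' warning.
#'
#' @param arcs An `arc_track`.
#' @param window [genomic_region()]; pairs entirely outside are dropped.
#' @param draw Draw onto the current device?
#' @return A data.frame with `x1`, `x2` (anchor midpoints), `height`,
#'   `lwd`, `skipped`, one row per pair considered.
#' @export
render_arcs_panel <- function(arcs, window, draw = FALSE) {
  stopifnot(inherits(arcs, "arc_track"))
  if (nrow(arcs) == 0L)
    return(data.frame(x1 = numeric(0), x2 = numeric(0), height = numeric(0),
                      lwd = numeric(0), skipped = logical(0)))
  x1 <- (arcs$start1 + arcs$end1) / 2
  x2 <- (arcs$start2 + arcs$end2) / 2
  inside <- pmax(x1, x2) > window$start & pmin(x1, x2) < window$end
  x1 <- x1[inside]; x2 <- x2[inside]
  score <- arcs$score[inside]
  skipped <- x1 == x2
  if (any(skipped))
    warning(sum(skipped), " degenerate arc(s) with coincident midpoints skipped")
  span <- abs(x2 - x1)
  height <- span / 2
  srange <- range(score[is.finite(score)], na.rm = TRUE)
  lwd <- if (diff(srange) > 0)
    1 + 2 * (score - srange[1]) / diff(srange) else rep(1.5, length(score))
  geom <- data.frame(x1 = x1, x2 = x2, height = height, lwd = lwd,
                     skipped = skipped)
  if (draw && any(!skipped)) {
    t <- seq(0, pi, length.out = 64)
    for (r in which(!skipped)) {
      cx <- (geom$x1[r] + geom$x2[r]) / 2
      graphics::lines(cx + (span[r] / 2) * cos(t), geom$height[r] * sin(t),
                      lwd = geom$lwd[r], col = "steelblue4")
    }
  }
  geom
}

#' Loop marker coordinates on a matrix panel
#'
#' Maps loci pairs to marker coordinates: on a heatmap panel, the marker
#' sits in the upper triangle at (bin of left-anchor midpoint, bin of
#' right-anchor midpoint); on a triangle panel at the rotation-convention
#' cell `(d, m) = (j - i, i + j)`.  Loops with an anchor outside the
#' window, or beyond a triangle panel's distance cap, are skipped with a
#' warning, never an error.
#'
#' @param loops An `arc_track` or data.frame with
#'   `start1/end1/start2/end2` columns.
#' @param window [genomic_region()] of the panel.
#' @param resolution Bin size of the matrix panel.
#' @param kind `"heatmap"` or `"triangle"`.
#' @param max_distance Distance cap for triangle panels.
#' @return A data.frame with `x`, `y` (marker coordinates: bins for
#'   heatmaps, `(m, d)` grid indices for triangles) and `drawn`.
#' @export
annotate_loops <- function(loops, window, resolution,
                           kind = c("heatmap", "triangle"),
                           max_distance = 8e6) {
  kind <- match.arg(kind)
  if (is.null(loops) || nrow(loops) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), drawn = logical(0)))
  m1 <- (loops$start1 + loops$end1) / 2
  m2 <- (loops$start2 + loops$end2) / 2
  lo <- pmin(m1, m2); hi <- pmax(m1, m2)
  inside <- lo >= window$start & hi <= window$end
  if (any(!inside))
    warning(sum(!inside), " loop(s) outside the window skipped")
  i <- bin_index(lo, window, resolution)     # 0-based bins
  j <- bin_index(hi, window, resolution)
  if (kind == "heatmap") {
    x <- i; y <- j                           # upper triangle: row < col
    drawn <- inside
  } else {
    d <- j - i
    capped <- d * resolution > max_distance
    if (any(capped & inside))
      warning(sum(capped & inside),
              " loop(s) beyond the triangle distance cap skipped")
    drawn <- inside & !capped
    x <- i + j; y <- d                       # midpoint-grid column, distance row
  }
  data.frame(x = x, y = y, drawn = drawn)
}

# ---- figure rendering ----------------------------------------------------

open_device <- function(path, width, height) {
  if (is.null(path)) { grDevices::pdf(NULL, width = width, height = height); return() }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height, units = "in",
                         res = 120),
    pdf = grDevices::pdf(path, width = width, height = height),
    svg = grDevices::svg(path, width = width, height = height),
    stop("unsupported output format '.", ext, "' (use png, pdf or svg)"))
}

matrix_color_range <- function(values, zlim, saturate = 0.98) {
  fin <- values[is.finite(values)]
  if (!is.null(zlim)) return(as.numeric(zlim))
  if (!length(fin)) return(c(0, 1))
  c(min(fin), as.numeric(stats::quantile(fin, saturate)))
}

panel_height <- function(kind) {
  switch(kind, heatmap = 4, triangle = 2.5, domains = 1.2, arcs = 1.2, 1)
}

#' Render a composed figure
#'
#' Draws the figure described by a [figure_spec()]: one column per
#' condition, panels stacked top to bottom in the given order, every panel
#' sharing the window's genomic x-range.  Highlights are translucent
#' vertical spans crossing every panel of every condition; loops are
#' markers on matrix panels.  Matrix color scales saturate at the 98th
#' percentile of in-window finite values (per panel, or globally with
#' `shared_color_scale`), so the diagonal does not drown the off-diagonal
#' structure; missing cells render grey, distinct from zero.
#'
#' The return value is a machine-readable layout report — the testable
#' rendering contract (pixel output is backend-dependent; the report is
#' not): per-panel kind, data x-range, color range, highlight count, loop
#' markers, and all warnings raised while drawing.
#'
#' @param spec A [figure_spec()].
#' @param report_path Optional path to also write the report as JSON.
#' @return The layout report (class `layout_report`), invisibly when a
#'   file is written.
#' @export
render_figure <- function(spec, report_path = NULL) {
  stopifnot(inherits(spec, "figure_spec"))
  window <- spec$window
  warn_log <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # precompute per-panel payloads clipped to the window
  prep <- list()
  for (cond in names(spec$conditions)) {
    for (pi in seq_along(spec$conditions[[cond]])) {
      p <- spec$conditions[[cond]][[pi]]
      item <- list(cond = cond, index = pi, spec = p)
      if (p$kind %in% c("heatmap", "triangle")) {
        item$sub <- collect(extract_submatrix(p$data, window))
        if (p$kind == "triangle")
          item$rot <- rotate_half_matrix(item$sub, p$max_distance)
      }
      prep[[length(prep) + 1L]] <- item
    }
  }
  # color ranges (matrix panels)
  is_mat <- vapply(prep, function(it) it$spec$kind %in% c("heatmap", "triangle"),
                   TRUE)
  if (spec$shared_color_scale && any(is_mat)) {
    allv <- unlist(lapply(prep[is_mat], function(it) it$sub$values))
    shared_range <- matrix_color_range(allv, NULL)
  } else shared_range <- NULL
  for (k in which(is_mat)) {
    prep[[k]]$zrange <- if (!is.null(prep[[k]]$spec$zlim))
      as.numeric(prep[[k]]$spec$zlim)
    else shared_range %||% matrix_color_range(prep[[k]]$sub$values, NULL)
  }

  # device and layout: one column per condition
  n_cond <- length(spec$conditions)
  max_rows <- max(vapply(spec$conditions, length, 1L))
  heights <- rep(1, max_rows)
  for (it in prep)
    heights[it$index] <- max(heights[it$index], panel_height(it$spec$kind))
  open_device(spec$output, width = 4.5 * n_cond,
              height = max(3, 0.9 * sum(heights)))
  on.exit(grDevices::dev.off(), add = TRUE)
  lay <- matrix(0L, nrow = max_rows, ncol = n_cond)
  cell <- 1L
  for (ci in seq_len(n_cond)) for (ri in seq_len(max_rows)) {
    lay[ri, ci] <- cell; cell <- cell + 1L
  }
  graphics::layout(lay, heights = heights)
  old_par <- graphics::par(mar = c(1.2, 3.2, 1.2, 0.6), mgp = c(2, 0.5, 0))
  on.exit(graphics::par(old_par), add = TRUE)

  pal <- grDevices::colorRampPalette(c("white", "red"))(256)
  xlim <- c(window$start, window$end)
  panels <- NULL
  loop_rows <- NULL

  for (cond in names(spec$conditions)) {
    items <- Filter(function(it) it$cond == cond, prep)
    for (ri in seq_len(max_rows)) {
      it <- if (ri <= length(items)) items[[ri]] else NULL
      if (is.null(it)) { graphics::plot.new(); next }
      p <- it$spec
      res <- if (!is.null(it$sub)) it$sub$resolution else NA_integer_
      ylim <- switch(p$kind,
        heatmap = xlim,
        triangle = c(0, min(p$max_distance,
                            (nrow(it$sub$values) - 1) * res)),
        histogram = p$ylim %||% {
          v <- p$data$value[p$data$start < window$end &
                            p$data$end > window$start]
          if (length(v)) c(min(0, min(v)), max(v) * 1.05) else c(0, 1)
        },
        tiles = c(0, 1),
        arcs = {
          g <- suppressWarnings(render_arcs_panel(p$data, window))
          c(0, max(g$height, 1))
        },
        domains = {
          g <- render_domains_panel(p$data, window)
          c(0, max(g$height, 1))
        })
      graphics::plot(NA, xlim = xlim, ylim = ylim, xaxs = "i",
                     yaxs = "i", xlab = "", ylab = "", axes = FALSE,
                     main = NULL)
      graphics::box(col = "grey60")
      graphics::mtext(p$label, side = 2, line = 0.4, cex = 0.55, las = 0)
      if (ri == 1)
        graphics::mtext(cond, side = 3, line = 0.2, cex = 0.7, font = 2)
      zrange <- it$zrange %||% c(NA_real_, NA_real_)

      collect(switch(p$kind,
        heatmap = draw_heatmap(it$sub, window, pal, zrange),
        triangle = draw_triangle(it$rot, window, pal, zrange, ylim),
        histogram = draw_histogram(p$data, window, p$color),
        tiles = draw_tiles(p$data, window),
        arcs = invisible(render_arcs_panel(p$data, window, draw = TRUE)),
        domains = invisible(render_domains_panel(p$data, window, draw = TRUE))))

      # highlights cross every panel
      for (h in spec$highlights)
        graphics::rect(max(h$start, window$start), ylim[1],
                       min(h$end, window$end), ylim[2],
                       col = grDevices::adjustcolor("palegreen3", 0.3),
                       border = NA)

      # loop markers on matrix panels
      if (!is.null(spec$loops) && p$kind %in% c("heatmap", "triangle")) {
        lm <- collect(annotate_loops(spec$loops, window, res, p$kind,
                                     p$max_distance))
        if (nrow(lm)) {
          if (p$kind == "heatmap") {
            gx <- window$start + (lm$x + 0.5) * res
            gy <- window$start + (lm$y + 0.5) * res
          } else {
            gx <- window$start + lm$x * res / 2
            gy <- lm$y * res
          }
          graphics::points(gx[lm$drawn], gy[lm$drawn], pch = 0, cex = 1.1,
                           col = "blue3", lwd = 1.4)
          loop_rows <- rbind(loop_rows,
            data.frame(condition = cond, panel = ri, kind = p$kind,
                       x = lm$x, y = lm$y, drawn = lm$drawn))
        }
      }
      panels <- rbind(panels, data.frame(
        condition = cond, panel = ri, kind = p$kind, label = p$label,
        x_min = xlim[1], x_max = xlim[2],
        color_min = zrange[1], color_max = zrange[2],
        max_distance = if (p$kind == "triangle") p$max_distance else NA_real_,
        rows_above_diagonal = if (p$kind == "triangle")
          nrow(it$rot$values) - 1L else NA_integer_,
        n_highlights = length(spec$highlights)))
    }
  }
  graphics::axis(1, cex.axis = 0.6)

  report <- structure(list(
    window = list(chrom = window$chrom, start = window$start,
                  end = window$end),
    n_conditions = n_cond,
    n_panels = nrow(panels),
    shared_color_scale = spec$shared_color_scale,
    panels = panels,
    highlights = lapply(spec$highlights, function(h)
      list(chrom = h$chrom, start = h$start, end = h$end)),
    loops = loop_rows %||% data.frame(),
    output = spec$output %||% NA_character_,
    warnings = warn_log), class = "layout_report")
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
    return(invisible(report))
  }
  report
}

draw_heatmap <- function(sub, window, pal, zrange) {
  n <- nrow(sub$values)
  edges <- sub$region$start + (0:n) * sub$resolution
  z <- pmin(pmax(sub$values, zrange[1]), zrange[2])
  graphics::rect(window$start, window$start, window$end, window$end,
                 col = "grey85", border = NA)        # NA cells show grey
  graphics::image(edges, edges, z, col = pal, zlim = zrange, add = TRUE,
                  useRaster = FALSE)
}

draw_triangle <- function(rot, window, pal, zrange, ylim) {
  n <- (ncol(rot$values) + 1L) %/% 2L
  res <- rot$resolution
  xs <- rot$region$start + (0:(2L * n - 1L)) * res / 2   # midpoint-grid edges
  D <- nrow(rot$values) - 1L
  ys <- (0:(D + 1L)) * res - res / 2
  z <- pmin(pmax(rot$values, zrange[1]), zrange[2])
  keep <- ys[-length(ys)] < ylim[2]
  graphics::image(xs, ys[c(which(keep), max(which(keep)) + 1L)],
                  t(z[keep, , drop = FALSE]), col = pal, zlim = zrange,
                  add = TRUE, useRaster = FALSE)
}

draw_histogram <- function(track, window, color) {
  keep <- track$start < window$end & track$end > window$start
  d <- track[keep, , drop = FALSE]
  if (!nrow(d)) return(invisible())
  graphics::rect(pmax(d$start, window$start), 0,
                 pmin(d$end, window$end), d$value, col = color, border = NA)
}

tile_palette <- function(labels) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#A65628", "#F781BF", "#999999")
  u <- unique(labels)
  stats::setNames(rep_len(base, length(u)), u)
}

draw_tiles <- function(track, window) {
  keep <- track$start < window$end & track$end > window$start
  d <- track[keep, , drop = FALSE]
  if (!nrow(d)) return(invisible())
  pal <- tile_palette(d$label)
  col <- ifelse(!is.na(d$color) & nzchar(d$color), d$color, pal[d$label])
  graphics::rect(pmax(d$start, window$start), 0.15,
                 pmin(d$end, window$end), 0.85, col = col, border = NA)
}

#' @export
print.layout_report <- function(x, ...) {
  cat(sprintf("<layout_report> %s:%d-%d  %d condition(s), %d panel(s)\n",
              x$window$chrom, x$window$start, x$window$end,
              x$n_conditions, x$n_panels))
  cat(sprintf("  highlights: %d; loops drawn: %d; warnings: %d\n",
              length(x$highlights),
              if (nrow(x$loops)) sum(x$loops$drawn) else 0L,
              length(x$warnings)))
  print(x$panels[, c("condition", "panel", "kind", "x_min", "x_max",
                     "color_min", "color_max")])
  invisible(x)
}
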