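make_window_fixture <- function(n = 40, seed = 21) {
  spec <- synthetic_spec(n_bins = n,
                         tads = data.frame(start_bin = floor(n * 0.2),
                                           end_bin = floor(n * 0.5),
                                           factor = 3), seed = seed)
  m <- generate_matrix(spec)
  sig <- generate_replication_signal(m$region, block_length_mean = 100e3,
                                     step = 25e3, seed = seed)
  tiles <- generate_state_tiles(m$region, seed = seed)
  arcs <- generate_anchors(sig, n_pairs = 10, bias = 0.5, seed = seed)
  list(m = m, sig = sig, tiles = tiles, arcs = arcs, window = m$region)
}

test_that("a minimal one-panel figure renders a valid image file", {
  fx <- make_window_fixture()
  out <- file.path(withr::local_tempdir(), "fig.png")
  spec <- figure_spec(fx$window, list(cond = list(panel_spec("heatmap", fx$m))),
                      output = out)
  rep <- render_figure(spec)
  expect_equal(rep$n_panels, 1)
  expect_equal(rep$panels$kind, "heatmap")
  expect_true(file.exists(out))
  expect_gt(file.info(out)$size, 1000)
  magic <- readBin(out, "raw", 8)           # PNG signature
  expect_identical(magic[2:4], as.raw(c(0x50, 0x4E, 0x47)))
})

test_that("shared color scale forces one range across all matrix panels", {
  fx <- make_window_fixture()
  m2 <- generate_matrix(synthetic_spec(n_bins = 40, base = 200, seed = 3))
  spec <- figure_spec(fx$window,
    list(A = list(panel_spec("heatmap", fx$m), panel_spec("histogram", fx$sig)),
         B = list(panel_spec("heatmap", m2), panel_spec("histogram", fx$sig))),
    shared_color_scale = TRUE)
  rep <- render_figure(spec)
  hm <- rep$panels[rep$panels$kind == "heatmap", ]
  expect_equal(nrow(hm), 2)
  expect_equal(hm$color_min[1], hm$color_min[2])
  expect_equal(hm$color_max[1], hm$color_max[2])
  all_vals <- c(fx$m$values, m2$values)
  expect_equal(hm$color_min[1], min(all_vals))
  expect_equal(hm$color_max[1], unname(stats::quantile(all_vals, 0.98)))

  # without the flag, differently scaled matrices get different ranges
  spec2 <- figure_spec(fx$window,
    list(A = list(panel_spec("heatmap", fx$m)),
         B = list(panel_spec("heatmap", m2))))
  rep2 <- render_figure(spec2)
  expect_false(isTRUE(all.equal(rep2$panels$color_max[1],
                                rep2$panels$color_max[2])))
})

test_that("a full multi-track figure keeps every panel on one x-axis", {
  fx <- make_window_fixture()
  stack <- function() list(
    panel_spec("heatmap", fx$m),
    panel_spec("histogram", fx$sig), panel_spec("histogram", fx$sig),
    panel_spec("histogram", fx$sig),
    panel_spec("tiles", fx$tiles), panel_spec("tiles", fx$tiles),
    panel_spec("tiles", fx$tiles),
    panel_spec("arcs", fx$arcs))
  hl <- list(genomic_region("chrS", 1e5, 2e5),
             genomic_region("chrS", 6e5, 7e5))
  spec <- figure_spec(fx$window, list(GM = stack(), K5 = stack()),
                      highlights = hl, shared_color_scale = TRUE)
  rep <- render_figure(spec)
  expect_equal(rep$n_panels, 16)
  expect_equal(unique(rep$panels$x_min), fx$window$start)
  expect_equal(unique(rep$panels$x_max), fx$window$end)
  expect_true(all(rep$panels$n_highlights == 2))
  expect_equal(length(rep$highlights), 2)
})

test_that("rendering the same spec twice yields identical reports", {
  fx <- make_window_fixture()
  spec <- figure_spec(fx$window,
    list(A = list(panel_spec("heatmap", fx$m), panel_spec("arcs", fx$arcs))),
    highlights = list(genomic_region("chrS", 2e5, 3e5)))
  expect_identical(render_figure(spec), render_figure(spec))
})

test_that("payloads that do not cover the window are coverage errors", {
  fx <- make_window_fixture()
  small <- extract_submatrix(fx$m, genomic_region("chrS", 0, 5e5))
  expect_error(
    figure_spec(fx$window, list(A = list(panel_spec("heatmap", small)))),
    "does not cover window")
  wrong_chrom <- histogram_track("chrZ", 0, 1e5, 1)
  expect_error(
    figure_spec(fx$window,
                list(A = list(panel_spec("histogram", wrong_chrom)))),
    "window is on")
  expect_error(figure_spec(fx$window, list()), "at least one condition")
  expect_error(panel_spec("heatmap", fx$sig), "does not match kind")
})

test_that("domain triangles have midpoint apexes and width-scaled heights", {
  r <- 5e4
  single <- domain_track("chrT", 0, 2 * r)
  g <- render_domains_panel(single, genomic_region("chrT", 0, 4 * r))
  expect_equal(g$apex_x, r)
  expect_equal(g$height, r)

  withr::local_seed(5)
  starts <- sort(sample(seq(0, 9e5, 1e4), 8))
  ends <- starts + sample(seq(2e4, 1e5, 1e4), 8, TRUE)
  t1 <- domain_track("chrT", starts, ends, "s1", "khaki3")
  t2 <- domain_track("chrT", starts, ends, "s2", "royalblue3")
  g2 <- render_domains_panel(list(t1, t2), genomic_region("chrT", 0, 1e6))
  expect_equal(nrow(g2), 16)
  expect_equal(g2$apex_x, rep((starts + ends) / 2, 2))
  expect_equal(g2$height, rep((ends - starts) / 2, 2))
  expect_equal(unique(g2$color), c("khaki3", "royalblue3"))
})

test_that("arc geometry scales height with span and skips degenerates", {
  w <- genomic_region("chrT", 0, 1e6)
  arcs <- arc_track("chrT", c(0, 0), c(2e4, 2e4), c(1e5, 2e5),
                    c(1.2e5, 2.2e5))     # midpoint spans 1e5 and 2e5
  g <- render_arcs_panel(arcs, w)
  expect_equal(g$height[2] / g$height[1], 2)

  degen <- arc_track("chrT", 100, 200, 100, 200)
  expect_warning(gd <- render_arcs_panel(degen, w), "degenerate")
  expect_true(gd$skipped)

  withr::local_seed(6)
  s1 <- sample(seq(0, 4e5, 1e4), 20); s2 <- s1 + sample(seq(5e4, 5e5, 1e4), 20, TRUE)
  many <- arc_track("chrT", s1, s1 + 1e4, s2, s2 + 1e4)
  gm <- render_arcs_panel(many, w)
  expect_equal(gm$x1, s1 + 5e3)
  expect_equal(gm$x2, s2 + 5e3)
})

test_that("loop markers land on the correct matrix cells", {
  w <- genomic_region("chrT", 0, 1e6)
  res <- 25e3
  # a loop on the diagonal sits at distance row 0 in triangle panels
  diag_loop <- arc_track("chrT", 1e5, 1.1e5, 1e5, 1.1e5)
  tri <- annotate_loops(diag_loop, w, res, "triangle")
  expect_equal(tri$y, 0)
  expect_true(tri$drawn)

  far <- arc_track("chrT", 0, 1e4, 9e5, 9.1e5)
  expect_warning(tc <- annotate_loops(far, w, res, "triangle",
                                      max_distance = 2e5), "distance cap")
  expect_false(tc$drawn)

  out <- arc_track("chrT", 0, 1e4, 1.5e6, 1.6e6)
  expect_warning(oc <- annotate_loops(out, w, res, "heatmap"),
                 "outside the window")
  expect_false(oc$drawn)

  withr::local_seed(8)
  s1 <- sample(seq(0, 4e5, 5e3), 15); s2 <- sample(seq(5e5, 9e5, 5e3), 15)
  loops <- arc_track("chrT", s1, s1 + 1e4, s2, s2 + 1e4)
  hm <- annotate_loops(loops, w, res, "heatmap")
  expect_equal(hm$x, floor((s1 + 5e3) / res))
  expect_equal(hm$y, floor((s2 + 5e3) / res))
  tr <- annotate_loops(loops, w, res, "triangle", max_distance = 8e6)
  expect_equal(tr$x, hm$x + hm$y)
  expect_equal(tr$y, hm$y - hm$x)
})

test_that("output format follows the file extension", {
  m <- small_interaction_matrix(10, 25000)
  dir <- withr::local_tempdir()
  spec_for <- function(p) figure_spec(
    m$region, list(A = list(panel_spec("heatmap", m))), output = p)
  pdf_path <- file.path(dir, "f.pdf")
  render_figure(spec_for(pdf_path))
  expect_identical(readBin(pdf_path, "raw", 4), charToRaw("%PDF"))
  expect_error(render_figure(spec_for(file.path(dir, "f.bmp"))),
               "unsupported output format")
})
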