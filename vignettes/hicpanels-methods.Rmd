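---
title: "Methods and design of hicpanels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of hicpanels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicpanels)
```

`hicpanels` integrates Hi-C contact matrices with linear genomic tracks in
aligned multi-condition figures and tests whether interaction anchors are
enriched for a continuous signal.  This vignette documents the methods, the
numerical conventions, and the design decisions that were genuinely open,
so that a user knows exactly what each number and pixel means.

## Coordinates and binning

All coordinates are 0-based, half-open `[start, end)`, the bedGraph/BED
convention, used uniformly from file parsing through rendering.  A position
`p` in a region starting at `s` with bin size `r` falls in bin
`floor((p - s)/r)`; a region of width `w` spans `ceiling(w/r)` bins, so a
trailing partial bin is kept rather than truncated.  Windows requested off
the bin grid are snapped *outward* (start down, end up) with a warning —
the alternative, snapping inward, silently drops requested base pairs.

## Matrix balancing

Sparse triplet files give raw observed contacts `O(i, j)` at bin start
coordinates; a companion vector gives one Knight–Ruiz balancing score per
bin, indexed from chromosome position 0.  The balanced matrix is
`O(i, j) / (KR(i) · KR(j))`, placed symmetrically.  Three conventions
matter:

* **Flagged scores.**  Scores that are missing (`NaN`) or non-positive
  mark bins where balancing is undefined (sparse or unmappable rows).
  Cells touched by a record involving such a bin become missing values.
  Mapping them to 0 instead would be indistinguishable from "no contact",
  which biases any downstream distance-decay or domain statistic, so
  missingness is propagated and rendered distinctly (grey, not white).
* **Duplicates.**  Duplicate records for one bin pair are summed *before*
  division — the behavior that is correct for concatenated dumps, and a
  no-op for well-formed input.  Records are canonicalized to the upper
  triangle first, so `(i, j)` and `(j, i)` duplicates also merge.
* **Bins without records are 0**, the sparse-format contract (absence
  means no observed contact, not missing data).

## The rotated half matrix

A symmetric matrix wastes half its area; the triangle display re-indexes
the upper triangle by distance and midpoint, `(i, j) → (d, m) = (j − i,
i + j)`, on a `(D + 1) × (2n − 1)` grid with `D = floor(max_distance /
resolution)`.  The integer midpoint grid (twice the bin frequency) was
chosen over resampling onto `n` columns because it is **lossless**: cells
of the wrong parity or beyond the sloping edges are missing, row 0 is
exactly the source diagonal, the finite-cell count is exactly
`Σ_{d=0..D} (n − d)`, and `unrotate()` reconstructs the band bit-for-bit.
Rendering then draws grid cells at half-bin width; information is only
reduced at the raster stage, never in the data structure.

The default cap is 8 Mb — the scale at which TAD-level structure lives and
the customary ceiling for triangle plots at 25-kb resolution (320 rows
above the diagonal).  Matrices asymmetric beyond a relative 1e-8 are
symmetrized by averaging with a warning: processed 5C/Hi-C text files
routinely carry float noise, and refusing them outright would help no one,
while silent acceptance would hide genuinely asymmetric (i.e. corrupted)
input.

## Track aggregation

A histogram track defines, at each base pair `x`, the sum `V(x)` of values
of covering intervals and the coverage count `C(x)`.  The
coverage-weighted mean over any query span is `∫V / ∫C`, equivalently
`Σ value·overlap_bp / Σ overlap_bp`.  This aggregator (rather than max or
sum) preserves the signal's scale across resolutions — a 25-kb bin mean of
a coverage track is still in coverage units — and makes mass conservation
an exact identity: `Σ_bins value·covered_bp = Σ_intervals
value·overlap_bp`.  Overlapping bedGraph intervals (non-standard but
common in practice) are therefore averaged by coverage weight rather than
rejected.  A `max` aggregator is available for sharp peaks that a mean
would dilute at coarse resolution.  Bins with no coverage are missing, not
zero.  The implementation flattens the track once into breakpoint-indexed
cumulative integrals, so each query is `O(log breakpoints)` — this is what
keeps the permutation test fast.

## Anchor enrichment test

The question: do interaction anchors (e.g. cohesin ChIA-PET loci) sit on
higher continuous signal (e.g. Repli-Seq replication timing) than chance
would place them?  The test:

1. Observed statistic: mean over anchors of each anchor's
   coverage-weighted mean signal.  Anchors without any signal coverage are
   excluded with a logged count.
2. Null: each of `N` permutations draws the same number of intervals,
   **length-matched one-to-one** to the observed anchors, with start
   positions uniform over the valid range of the region.  Draws may
   overlap one another — this is the simplest exchangeable null; forcing
   disjointness would both complicate sampling and slightly bias the null
   toward dispersed (typically lower-signal) placements.
3. One-sided empirical p-value with the add-one correction,
   `p = (1 + #{random mean ≥ observed}) / (N + 1)`, never exactly zero and
   uniform on `{1/(N+1), …, 1}` under the null.  A two-sided variant
   doubles the smaller tail.

The test is directional by default because the scientific question it
serves is directional (enrichment, not mere difference).  The
whole-region coverage-weighted mean is reported as the background level;
for a single anchor covering the whole region the observed mean equals the
background and `p = 1`, since every permutation reproduces the region
itself.

## Synthetic data: what it emulates, what it does not

The generators produce every input dialect the readers consume, so the
full pipeline runs and is tested without downloads.

* **Contact matrices** follow `E[M_ij] = base·(1 + |i − j|)^(−α)`, times a
  factor `> 1` when `i, j` share a planted TAD, with multiplicative
  lognormal noise (contacts are positive; log-scale noise is the natural
  multiplicative error model for count-derived ratios).  Defaults:
  `α = 1` (typical of mammalian sub-megabase decay), `base = 1000`
  (keeps values in a realistic 0–1000 range), `noise_sd = 0.2`,
  resolution 25 kb.  At `noise_sd = 0` the closed form is exact, which the
  tests exploit.
* **Replication timing** is a two-state (early/late) piecewise-constant
  track with geometric block lengths (mean 500 kb by default, the scale of
  replication domains) at levels 60/20 plus small Gaussian noise.
* **Anchors** are placed, with probability `bias`, uniformly inside two
  distinct early blocks, otherwise uniformly anywhere (spanning at least
  one block boundary).  `bias = 0.9` with a 2× early/late signal ratio is
  the planted-effect condition used in the recovery checks.
* **State tiles** are an exact partition with sampled labels, emulating a
  ChromHMM-style segmentation.

What the generators do **not** emulate: A/B compartment checkerboards,
loop-peak point enrichments, copy-number steps, mappability gaps,
chromosome-wide coverage biases, or correlated noise between conditions.
Tests passing on this synthetic structure demonstrate that the mechanics
(parsing, balancing, re-indexing, binning, layout, permutation
calibration) are correct — not that any biological inference drawn from a
particular real dataset is.

## Rendering and the layout report

Figures are described declaratively (`figure_spec`): conditions are
columns, panels are stacked rows, all panels share the window's genomic
x-range as their user coordinate system, which makes cross-panel alignment
structural rather than something to calibrate.  The tested contract is the
**layout report** — panel kinds, x-ranges, color ranges, highlight counts,
loop markers, warnings — because pixel output varies by graphics backend
while geometry does not.  Rendering is deterministic: the same spec and
data give a byte-identical report.

Matrix color scales default to white→red with the upper limit at the 98th
percentile of in-window finite values; without saturation the diagonal
dominates and all off-diagonal structure washes out.  With
`shared_color_scale` the percentile is taken over all matrix panels
jointly, making cross-condition intensity comparable.  Missing cells are
grey, zeros are white.  Domains are drawn as isoceles triangles (apex at
the midpoint, height = half the width, i.e. 45° slopes); arcs as
semi-ellipses of height proportional to the midpoint span, score mapped to
line width; degenerate arcs (coincident midpoints) and loops outside the
window or beyond a triangle's cap are skipped with warnings, never errors
— a figure with one bad annotation should still render.

## Problem sizes in the checks

The verification suite runs 100-instance sweeps for each exact oracle
(balancing vs per-record brute force at ≤ 50 bins; rotation vs double-loop
placement at ≤ 30 bins; binning vs base-pair accumulation on ≤ 2.5-kb toy
regions), a 16-panel two-condition composite for the layout contract, and
for the enrichment test a 20-Mb region with 200 planted anchors at 999
permutations plus a 200-repeat null calibration at 199 permutations
(p-values there live on a grid of 1/200, fine enough for a
Kolmogorov–Smirnov uniformity check).  These sizes give each property
enough instances to fail loudly while the whole suite stays fast enough to
run on every change.

## Known limitations

* Single-chromosome windows only: no interchromosomal or whole-genome
  montage views.
* Balancing factors are applied, never computed; no `.hic`/`.cool`
  support (plain-text dialects only).
* The enrichment null randomizes interval *positions* uniformly; it does
  not preserve distance-to-nearest-anchor structure or chromosome-wide
  signal autocorrelation beyond what length-matching captures.  For
  strongly autocorrelated signals the test is anti-conservative relative
  to a block-permutation null; interpret borderline p-values accordingly.
* Histogram panels draw raw intervals; extremely dense tracks should be
  pre-binned with `bin_signal()` for speed, which is also how the matrix
  resolution display is produced.
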