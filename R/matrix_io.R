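#' Interaction matrix
#'
#' A square symmetric Hi-C contact matrix anchored at a genomic origin with
#' a fixed bin resolution.  Bin `i` (0-based) covers
#' `[region$start + i*resolution, region$start + (i+1)*resolution)`.
#'
#' @param region [genomic_region()] the matrix covers.
#' @param resolution Bin size in base pairs.
#' @param values `n x n` numeric matrix, `n = ceiling(width/resolution)`.
#'   `NA` marks missing (e.g. unbalanced) cells, distinct from 0 contacts.
#' @param label Condition name used in figure panels.
#' @param sym_tol Relative tolerance for the symmetry check; matrices
#'   asymmetric beyond it are symmetrized by averaging with a warning
#'   (processed inputs can carry float noise).
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(region, resolution, values, label = "",
                               sym_tol = 1e-8) {
  stopifnot(inherits(region, "genomic_region"), resolution > 0)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("interaction matrix must be square, got ",
         nrow(values), "x", ncol(values))
  n_expected <- n_bins(region, resolution)
  if (nrow(values) != n_expected)
    stop(sprintf(
      "matrix dimension inconsistent with region/resolution: expected %d bins for %s at %d bp, found %d",
      n_expected, format(region), as.integer(resolution), nrow(values)))
  fin <- is.finite(values)
  if (any(values[fin] < 0))
    stop("interaction matrix entries must be non-negative")
  scale <- max(abs(values[fin]), 1)
  asym <- abs(values - t(values))
  if (any(asym[is.finite(asym)] > sym_tol * scale)) {
    warning("matrix asymmetric beyond tolerance; symmetrized by averaging")
    values <- (values + t(values)) / 2
  }
  structure(list(region = region, resolution = as.integer(resolution),
                 values = values, label = label),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %s  %d x %d bins @ %s bp%s\n",
              format(x$region), nrow(x$values), ncol(x$values),
              format(x$resolution, big.mark = ","),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  n_fin <- sum(is.finite(x$values))
  cat(sprintf("  finite cells: %d/%d; range %s\n", n_fin, length(x$values),
              if (n_fin) paste(signif(range(x$values, na.rm = TRUE), 4),
                               collapse = " - ") else "NA"))
  invisible(x)
}

#' @export
dim.interaction_matrix <- function(x) dim(x$values)

#' Read a dense whitespace-delimited interaction matrix
#'
#' The file holds one matrix row per line, columns separated by any run of
#' spaces or tabs.  Non-numeric cells (`NaN`, `nan`, `NA`) become missing
#' values.  An optional header row and/or leading label column is detected
#' by a non-numeric first token and skipped with a warning.
#'
#' @param path Path to the matrix file.
#' @param region [genomic_region()] the matrix covers.
#' @param resolution Bin size in base pairs; the file's row count must equal
#'   `ceiling(width/resolution)`.
#' @param label Condition name.
#' @return An [interaction_matrix()].
#' @export
read_dense_matrix <- function(path, region, resolution, label = "") {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) stop("empty matrix file: ", path)
  toks <- lapply(dat$lines, split_ws)
  lineno <- dat$lineno

  # header row: first token of first line not numeric-like
  if (!is_numeric_token(toks[[1]][1]) &&
      length(toks) > 1L && is_numeric_token(toks[[2]][length(toks[[2]])])) {
    warning("non-numeric header row detected in ", path, "; skipped")
    toks <- toks[-1L]
    lineno <- lineno[-1L]
  }
  # header column: every remaining line starts with a non-numeric token
  if (all(vapply(toks, function(t) !is_numeric_token(t[1]), logical(1)))) {
    warning("non-numeric leading column detected in ", path, "; skipped")
    toks <- lapply(toks, function(t) t[-1L])
  }

  widths <- lengths(toks)
  if (length(unique(widths)) != 1L) {
    # the first row defines the expected width
    bad <- which(widths != widths[1])[1]
    stop(sprintf(
      "ragged rows in %s: line %d has %d columns, expected %d",
      path, lineno[bad], widths[bad], widths[1]))
  }
  n <- length(toks)
  if (widths[1] != n)
    stop(sprintf("matrix in %s is not square: %d rows x %d columns",
                 path, n, widths[1]))
  values <- matrix(as_numeric_na(unlist(toks)), nrow = n, byrow = TRUE)
  bad_cell <- which(is.na(values) &
                    !(matrix(unlist(toks), nrow = n, byrow = TRUE) %in%
                      c("NaN", "nan", "NA", "na", ".")))
  if (length(bad_cell))
    stop("non-numeric cell in ", path, " that is not a missing-value marker")
  interaction_matrix(region, resolution, values, label)
}

#' Write a dense matrix file
#'
#' Inverse of [read_dense_matrix()]: plain-text whitespace-delimited rows,
#' missing values written as `NaN`.
#'
#' @param matrix An [interaction_matrix()] (or bare numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(matrix, path) {
  values <- if (inherits(matrix, "interaction_matrix")) matrix$values else matrix
  txt <- apply(values, 1L, function(row) {
    row <- ifelse(is.na(row), "NaN", format(row, digits = 17, trim = TRUE,
                                            scientific = FALSE))
    paste(row, collapse = "\t")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Read sparse triplet contacts
#'
#' Parses the 3-column intrachromosomal dump dialect
#' (`locus_i locus_j raw_count` per line, loci as genomic start coordinates
#' of the contacting bins).  All records are retained in file order,
#' including diagonal records.
#'
#' @param path Path to the contacts file.
#' @return An object of class `sparse_contacts`: a data.frame with columns
#'   `i`, `j` (base pairs) and `count`.
#' @export
read_sparse_contacts <- function(path) {
  dat <- read_data_lines(path)
  n <- length(dat$lines)
  if (n == 0L) {
    out <- data.frame(i = numeric(0), j = numeric(0), count = numeric(0))
    class(out) <- c("sparse_contacts", "data.frame")
    return(out)
  }
  toks <- lapply(dat$lines, split_ws)
  for (k in seq_len(n)) {
    t <- toks[[k]]
    if (length(t) < 3L)
      stop(sprintf("line %d of %s: expected 'locus_i locus_j count', got %d fields",
                   dat$lineno[k], path, length(t)))
    num <- suppressWarnings(as.numeric(t[1:3]))
    if (any(is.na(num)))
      stop(sprintf("line %d of %s: non-numeric field", dat$lineno[k], path))
    if (num[1] != floor(num[1]) || num[2] != floor(num[2]) ||
        num[1] < 0 || num[2] < 0)
      stop(sprintf("line %d of %s: loci must be non-negative integers",
                   dat$lineno[k], path))
    if (num[3] < 0)
      stop(sprintf("line %d of %s: negative count %s",
                   dat$lineno[k], path, t[3]))
  }
  m <- matrix(as.numeric(unlist(lapply(toks, `[`, 1:3))), ncol = 3,
              byrow = TRUE)
  out <- data.frame(i = m[, 1], j = m[, 2], count = m[, 3])
  class(out) <- c("sparse_contacts", "data.frame")
  out
}

#' Write sparse triplet contacts
#' @param contacts A `sparse_contacts` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparse_contacts <- function(contacts, path) {
  utils::write.table(as.data.frame(contacts)[, c("i", "j", "count")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a per-bin normalization vector
#'
#' One balancing score per line; line `k` is the score of bin `k - 1`,
#' i.e. chromosome position `(k-1) * resolution`.  Literal `NaN` (and
#' non-positive scores) mark bins for which balancing is undefined; they
#' are flagged rather than used.
#'
#' @param path Path to the vector file.
#' @param resolution Bin size in base pairs the vector was computed at.
#' @return An object of class `norm_vector`: list with `resolution` and
#'   numeric `scores` (`NA` where flagged).
#' @export
read_norm_vector <- function(path, resolution) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]          # trailing blanks only
  scores <- as_numeric_na(lines)
  bad <- which(is.na(scores) & !(lines %in% c("NaN", "nan", "NA", "na", "", ".")))
  if (length(bad))
    stop(sprintf("line %d of %s: non-numeric score '%s'",
                 bad[1], path, lines[bad[1]]))
  norm_vector(scores, resolution)
}

#' @rdname read_norm_vector
#' @param scores Numeric vector of per-bin scores (may contain `NA`).
#' @export
norm_vector <- function(scores, resolution) {
  stopifnot(resolution > 0)
  scores <- as.numeric(scores)
  flagged <- !is.finite(scores) | scores <= 0
  scores[flagged] <- NA_real_
  structure(list(resolution = as.integer(resolution), scores = scores),
            class = "norm_vector")
}

#' Apply Knight-Ruiz balancing to sparse contacts
#'
#' Builds the balanced dense matrix over `region` from raw sparse records:
#' each observed count `O(i, j)` is divided by the product of the per-bin
#' balancing scores, `O(i, j) / (KR(i) * KR(j))`, and placed symmetrically.
#' Bins touched by a record whose balancing score is flagged (missing or
#' non-positive) yield missing cells — not zeros, which would masquerade as
#' "no contact".  Bins with no record are 0.  Duplicate records for the
#' same bin pair are summed before normalization.
#'
#' @param contacts A `sparse_contacts` object ([read_sparse_contacts()]).
#' @param norm A `norm_vector` ([read_norm_vector()]); its resolution must
#'   match `resolution`.  Scores are indexed from chromosome position 0.
#' @param region [genomic_region()] to build; must be aligned to the
#'   resolution grid.  Records with either locus outside are dropped.
#' @param resolution Bin size in base pairs.
#' @param label Condition name for the resulting matrix.
#' @return An [interaction_matrix()].
#' @export
normalize_contacts <- function(contacts, norm, region, resolution,
                               label = "") {
  stopifnot(inherits(contacts, "sparse_contacts"),
            inherits(norm, "norm_vector"))
  resolution <- as.integer(resolution)
  if (norm$resolution != resolution)
    stop("normalization vector resolution (", norm$resolution,
         ") does not match requested resolution (", resolution, ")")
  if (region$start %% resolution != 0 || region$end %% resolution != 0)
    stop("region ", format(region), " is not aligned to the ",
         resolution, "-bp grid")
  mis <- which(contacts$i %% resolution != 0 | contacts$j %% resolution != 0)
  if (length(mis))
    stop(sprintf(
      "record %d: locus (%s, %s) not a multiple of resolution %d",
      mis[1], format(contacts$i[mis[1]], scientific = FALSE),
      format(contacts$j[mis[1]], scientific = FALSE), resolution))

  n <- n_bins(region, resolution)
  inside <- contacts$i >= region$start & contacts$i < region$end &
            contacts$j >= region$start & contacts$j < region$end
  rec <- contacts[inside, , drop = FALSE]
  values <- matrix(0, n, n)
  if (nrow(rec)) {
    # absolute bin numbers index the KR vector; relative ones the matrix
    abs_i <- rec$i %/% resolution
    abs_j <- rec$j %/% resolution
    need <- max(abs_i, abs_j) + 1L
    if (need > length(norm$scores))
      stop(sprintf(
        "normalization vector too short: bin %d needed, only %d scores",
        need - 1L, length(norm$scores)))
    b1 <- (rec$i - region$start) %/% resolution + 1L
    b2 <- (rec$j - region$start) %/% resolution + 1L
    bi <- pmin(b1, b2)                      # canonical upper-triangle pair
    bj <- pmax(b1, b2)
    kr <- norm$scores[abs_i + 1L] * norm$scores[abs_j + 1L]
    val <- rec$count / kr          # NA where either score is flagged
    # duplicates: sum raw counts first, then divide once (kr is per-pair)
    key <- paste(bi, bj)
    agg_count <- rowsum(rec$count, key, reorder = FALSE)
    agg_kr <- kr[!duplicated(key)]
    ord <- match(rownames(agg_count), key[!duplicated(key)])
    stopifnot(!anyNA(ord))
    pair <- do.call(rbind, lapply(strsplit(rownames(agg_count), " "),
                                  as.integer))
    vals <- as.numeric(agg_count) / agg_kr[ord]
    values[cbind(pair[, 1], pair[, 2])] <- vals
    values[cbind(pair[, 2], pair[, 1])] <- vals
  }
  interaction_matrix(region, resolution, values, label)
}

#' Extract a genomic window from an interaction matrix
#'
#' Returns the principal submatrix covering `window`.  Window boundaries
#' off the resolution grid are snapped outward ([snap_region()]) with a
#' warning, so no requested base pair is dropped.  Symmetry and missing
#' values are preserved.
#'
#' @param matrix An [interaction_matrix()].
#' @param window [genomic_region()] contained in `matrix$region`.
#' @return An [interaction_matrix()] covering the snapped window.
#' @export
extract_submatrix <- function(matrix, window) {
  stopifnot(inherits(matrix, "interaction_matrix"),
            inherits(window, "genomic_region"))
  reg <- matrix$region
  res <- matrix$resolution
  if (!region_contains(reg, window))
    stop(sprintf("window %s is outside matrix region %s",
                 format(window), format(reg)))
  # snap relative to the matrix's own grid origin
  rel <- genomic_region(window$chrom, window$start - reg$start,
                        window$end - reg$start)
  rel <- snap_region(rel, res)
  first <- rel$start %/% res + 1L
  last <- min(rel$end %/% res, nrow(matrix$values))
  out_region <- genomic_region(reg$chrom, reg$start + rel$start,
                               reg$start + last * res)
  interaction_matrix(out_region, res,
                     matrix$values[first:last, first:last, drop = FALSE],
                     matrix$label)
}
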