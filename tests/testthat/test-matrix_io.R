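test_that("dense matrix files read back verbatim, with NaN as missing", {
  f <- withr::local_tempfile()
  writeLines(c("0 1 2", "1 0 3", "2 3 0"), f)
  m <- read_dense_matrix(f, genomic_region("chrT", 0, 75000), 25000)
  expect_equal(m$values, matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
  expect_true(isSymmetric(m$values))

  writeLines(c("0\tNaN", "NaN\t5"), f)
  m2 <- read_dense_matrix(f, genomic_region("chrT", 0, 50000), 25000)
  expect_identical(is.na(m2$values), matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
})

test_that("malformed dense files fail loudly with the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("0 1 2", "1 0"), f)
  expect_error(read_dense_matrix(f, genomic_region("chrT", 0, 50000), 25000),
               "line 2")
  writeLines(c("0 1", "1 0"), f)
  expect_error(read_dense_matrix(f, genomic_region("chrT", 0, 75000), 25000),
               "expected 3 bins.*found 2")
})

test_that("header row/column are auto-detected and skipped", {
  f <- withr::local_tempfile()
  writeLines(c("binA binB", "binA 0 4", "binB 4 0"), f)
  expect_warning(expect_warning(
    m <- read_dense_matrix(f, genomic_region("chrT", 0, 50000), 25000),
    "header row"), "leading column")
  expect_equal(m$values, matrix(c(0, 4, 4, 0), 2))
})

test_that("a written synthetic matrix reads back exactly", {
  withr::local_seed(11)
  m <- generate_matrix(synthetic_spec(n_bins = 40, noise_sd = 0.3, seed = 5))
  f <- withr::local_tempfile()
  write_dense_matrix(m, f)
  m2 <- read_dense_matrix(f, m$region, m$resolution)
  expect_identical(m2$values, m$values)
})

test_that("sparse contact parsing keeps records, order, and diagonals", {
  f <- withr::local_tempfile()
  writeLines("0\t25000\t10", f)
  ct <- read_sparse_contacts(f)
  expect_equal(nrow(ct), 1)
  expect_equal(as.numeric(ct[1, ]), c(0, 25000, 10))

  writeLines(character(0), f)
  expect_equal(nrow(read_sparse_contacts(f)), 0)

  writeLines(c("0 0 5", "25000 50000 2.5", "0 25000 1"), f)
  ct <- read_sparse_contacts(f)
  expect_equal(ct$count, c(5, 2.5, 1))
  expect_equal(ct$i[1], ct$j[1])           # diagonal retained

  writeLines(c("0 25000 3", "0 25000 -1"), f)
  expect_error(read_sparse_contacts(f), "line 2.*negative count")
  writeLines("0 12.5 3", f)
  expect_error(read_sparse_contacts(f), "non-negative integers")
})

test_that("KR normalization matches the analytic 2-bin case", {
  f <- withr::local_tempfile()
  writeLines("0\t25000\t10", f)
  ct <- read_sparse_contacts(f)
  nv <- norm_vector(c(2, 5), 25000)
  m <- normalize_contacts(ct, nv, genomic_region("chrT", 0, 50000), 25000)
  expect_equal(m$values, matrix(c(0, 1, 1, 0), 2))
})

test_that("unit KR vector reproduces raw counts exactly", {
  withr::local_seed(3)
  region <- genomic_region("chrT", 0, 20 * 25000)
  n_rec <- 80
  i <- sample(0:19, n_rec, TRUE) * 25000
  j <- sample(0:19, n_rec, TRUE) * 25000
  ct <- structure(data.frame(i = pmin(i, j), j = pmax(i, j),
                             count = rpois(n_rec, 20)),
                  class = c("sparse_contacts", "data.frame"))
  m <- normalize_contacts(ct, norm_vector(rep(1, 20), 25000), region, 25000)
  expect_identical(m$values, brute_normalize(ct, rep(1, 20), region, 25000))
})

test_that("normalization equals brute-force per-record construction", {
  withr::local_seed(17)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    res <- 25000
    offset <- sample(0:3, 1) * res          # region not at chromosome start
    region <- genomic_region("chrT", offset, offset + n * res)
    n_rec <- sample(1:120, 1)
    i <- sample(0:(n + 3), n_rec, TRUE) * res  # some records out of range
    j <- sample(0:(n + 3), n_rec, TRUE) * res
    ct <- structure(data.frame(i = i, j = j,
                               count = round(runif(n_rec, 0, 50), 2)),
                    class = c("sparse_contacts", "data.frame"))
    kr <- runif(n + 4, 0.2, 3)
    kr[sample(length(kr), 1)] <- NA          # one flagged bin
    m <- normalize_contacts(ct, norm_vector(kr, res), region, res)
    expect_equal(m$values, brute_normalize(ct, kr, region, res),
                 tolerance = 1e-12)
  }
})

test_that("flagged KR bins propagate as missing, not zero", {
  f <- withr::local_tempfile()
  writeLines(c("2", "NaN", "0.5"), f)
  nv <- read_norm_vector(f, 25000)
  expect_true(is.na(nv$scores[2]))
  ct <- structure(data.frame(i = c(0, 25000), j = c(25000, 50000),
                             count = c(4, 4)),
                  class = c("sparse_contacts", "data.frame"))
  m <- normalize_contacts(ct, nv, genomic_region("chrT", 0, 75000), 25000)
  # both records touch the flagged bin 1 (0-based): their cells are NA
  expect_true(is.na(m$values[1, 2]))
  expect_true(is.na(m$values[2, 3]))
  expect_equal(m$values[1, 3], 0)           # untouched cells stay zero
})

test_that("misaligned loci and short KR vectors are rejected", {
  ct <- structure(data.frame(i = 100, j = 25000, count = 1),
                  class = c("sparse_contacts", "data.frame"))
  expect_error(normalize_contacts(ct, norm_vector(c(1, 1), 25000),
                                  genomic_region("chrT", 0, 50000), 25000),
               "not a multiple of resolution")
  ct2 <- structure(data.frame(i = 0, j = 75000, count = 1),
                   class = c("sparse_contacts", "data.frame"))
  expect_error(normalize_contacts(ct2, norm_vector(c(1, 1), 25000),
                                  genomic_region("chrT", 0, 100000), 25000),
               "too short.*bin 3")
})

test_that("duplicate records are summed before normalization", {
  ct <- structure(data.frame(i = c(0, 25000, 0), j = c(25000, 0, 25000),
                             count = c(1, 2, 3)),
                  class = c("sparse_contacts", "data.frame"))
  m <- normalize_contacts(ct, norm_vector(c(2, 2), 25000),
                          genomic_region("chrT", 0, 50000), 25000)
  expect_equal(m$values[1, 2], 6 / 4)
})

test_that("submatrix extraction is exact index slicing", {
  withr::local_seed(23)
  m <- small_interaction_matrix(40, 25000)

  full <- extract_submatrix(m, m$region)
  expect_identical(full$values, m$values)

  one <- extract_submatrix(m, genomic_region("chrT", 5 * 25000, 6 * 25000))
  expect_equal(one$values, m$values[6, 6, drop = FALSE])

  for (rep in 1:20) {
    a <- sample(0:30, 1)
    w <- genomic_region("chrT", a * 25000, (a + 10) * 25000)
    sub <- extract_submatrix(m, w)
    expect_identical(sub$values, m$values[(a + 1):(a + 10), (a + 1):(a + 10)])
    expect_true(isSymmetric(sub$values))
  }
  expect_error(extract_submatrix(m, genomic_region("chrT", 0, 2e6)),
               "outside matrix region")
})

test_that("extraction preserves missing cells and snaps off-grid windows", {
  vals <- random_symmetric_matrix(6)
  vals[2, 4] <- vals[4, 2] <- NA
  m <- interaction_matrix(genomic_region("chrT", 0, 6000), 1000, vals)
  expect_warning(sub <- extract_submatrix(m, genomic_region("chrT", 1500, 4500)),
                 "snapped")
  expect_equal(sub$region$start, 1000)
  expect_equal(sub$region$end, 5000)
  expect_true(is.na(sub$values[2 - 1, 4 - 1]))
})
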