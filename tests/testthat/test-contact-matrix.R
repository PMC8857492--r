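test_that("TSV round-trip preserves counts, binning and chromosome", {
  m <- toy_matrix(10, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(m, path)
  m2 <- read_contact_matrix(path)
  expect_equal(m2$counts, m$counts)
  expect_identical(m2$bin_size, m$bin_size)
  expect_identical(m2$chrom, m$chrom)
})

test_that("sparse upper-triangle records materialize a symmetric matrix", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chr2\t5000\t4", "0\t1\t3", "1\t3\t2", "2\t2\t7"), path)
  m <- read_contact_matrix(path)
  expect_equal(m$counts, t(m$counts))
  expect_equal(m$counts[1, 2], 3)
  expect_equal(m$counts[2, 1], 3)
  expect_equal(m$counts[3, 3], 7)
  expect_equal(total_counts(m), 12)
})

test_that("malformed records are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chr1\t5000\t4", "0\t1\t3", "1\t9\t2"), path)
  expect_error(read_contact_matrix(path), "line 3")
  writeLines(c("#chr1\t5000\t4", "2\t1\t3"), path)
  expect_error(read_contact_matrix(path), "lower-triangle")
  writeLines(c("#chr1\t5000\t4", "0\t1\t-3"), path)
  expect_error(read_contact_matrix(path), "negative")
})

test_that("constructor validates symmetry and sign", {
  x <- matrix(1:9, 3, 3)
  expect_error(contact_matrix(x), "symmetric")
  y <- diag(3); y[1, 2] <- y[2, 1] <- -1
  expect_error(contact_matrix(y), "negative")
})

test_that("low-coverage masking follows the nonzero-marginal quantile rule", {
  x <- toy_counts(10, seed = 2)
  x[4, ] <- 0; x[, 4] <- 0
  m <- contact_matrix(x)
  expect_equal(which(mask_low_coverage(m, 0)$mask), 4L)

  u <- contact_matrix(matrix(2, 8, 8))
  expect_false(any(mask_low_coverage(u, 0)$mask))

  # one tenth of bins at clearly low coverage: q = 0.1 masks about that many
  withr::with_seed(9, {
    n <- 100
    x <- matrix(stats::rpois(n * n, 20), n, n); x <- x + t(x)
    low <- sample.int(n, 10)
    x[low, ] <- x[low, ] %/% 10
    x[, low] <- t(x[low, , drop = FALSE])
  })
  m <- contact_matrix(x)
  marg <- rowSums(x)
  oracle <- which(marg == 0 | marg < quantile(marg[marg > 0], 0.1,
                                              names = FALSE))
  expect_equal(which(mask_low_coverage(m, 0.1)$mask), oracle)
  expect_gte(length(oracle), 8)
})

test_that("ICE balancing equalizes row sums and handles masked bins", {
  # equal row sums in, equal weights out, balanced proportional to input
  m <- prep_matrix(contact_matrix(matrix(3, 5, 5)), q = 0)
  expect_lt(diff(range(m$weights)), 1e-8)
  expect_lt(diff(range(balanced_values(m) / 3)), 1e-8)

  # 2x2 fixed-point oracle, iterated independently to 1e-12
  x <- matrix(c(4, 2, 2, 1), 2, 2)
  w <- c(1, 1)
  for (i in 1:10000) {
    s <- rowSums(x * outer(w, w))
    if (sd(s) / mean(s) < 1e-12) break
    w <- w / s
    w <- w / mean(w)
  }
  w <- w / sqrt(mean(rowSums(x * outer(w, w))))
  m2 <- ice_balance(contact_matrix(x), tol = 1e-12)
  expect_equal(m2$weights, w, tolerance = 1e-9)
  s2 <- rowSums(balanced_values(m2))
  expect_lt(abs(s2[1] - s2[2]), 1e-10)

  # masked bin: excluded from balancing, NA weight
  x <- toy_counts(8, seed = 3)
  m3 <- contact_matrix(x)
  m3$mask[5] <- TRUE
  m3 <- ice_balance(m3)
  expect_true(is.na(m3$weights[5]))
  expect_true(all(is.na(balanced_values(m3)[5, ])))
  rs <- rowSums(balanced_values(m3), na.rm = TRUE)[!m3$mask]
  expect_lt(sd(rs) / mean(rs), 1e-6)
})

test_that("expected profile matches direct enumeration", {
  v <- c(8, 5, 3, 2, 1)
  m <- prep_matrix(toeplitz_matrix(v), q = 0)
  E <- expected_profile(m, use_balanced = FALSE)
  expect_equal(E, v)

  m <- toy_matrix(12, seed = 4)
  m$mask[c(2, 7)] <- TRUE
  m <- ice_balance(m)
  E <- expected_profile(m)
  b <- balanced_values(m)
  n <- n_bins(m)
  for (d in c(0, 1, 3, 11)) {
    cells <- c()
    for (i in seq_len(n - d)) {
      if (!m$mask[i] && !m$mask[i + d]) cells <- c(cells, b[i, i + d])
    }
    expect_equal(E[d + 1], mean(cells))
  }
})

test_that("observed-over-expected has unit diagonal means and Toeplitz identity", {
  m <- mask_low_coverage(toeplitz_matrix(c(9, 6, 4, 2, 1)), 0)
  oe <- observed_over_expected(m, use_balanced = FALSE)
  expect_true(all(abs(oe - 1) < 1e-9))

  m <- toy_matrix(15, seed = 5)
  m$mask[3] <- TRUE
  m <- ice_balance(m)
  oe <- observed_over_expected(m)
  n <- n_bins(m)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    v <- oe[cbind(i, i + d)]
    v <- v[!is.na(v)]
    if (length(v)) expect_lt(abs(mean(v) - 1), 1e-9)
  }
})

test_that("merging sums counts and conserves totals", {
  m <- toy_matrix(8, seed = 6)
  zero <- contact_matrix(matrix(0, 8, 8))
  expect_equal(merge_matrices(list(m, zero))$counts, m$counts)
  expect_equal(merge_matrices(list(m, m))$counts, 2 * m$counts)
  m2 <- toy_matrix(8, seed = 7)
  expect_equal(total_counts(merge_matrices(list(m, m2))),
               total_counts(m) + total_counts(m2))
  expect_error(merge_matrices(list(m, toy_matrix(9))), "shape")
})

test_that("subsampling hits the target exactly, preserves symmetry, is unbiased", {
  m <- toy_matrix(10, seed = 8)
  tot <- total_counts(m)
  expect_equal(subsample_counts(m, tot)$counts, m$counts)
  expect_equal(total_counts(subsample_counts(m, 0, seed = 1)), 0)
  expect_error(subsample_counts(m, tot + 1), "exceeds")

  target <- round(tot / 3)
  sub <- subsample_counts(m, target, seed = 1)
  expect_equal(total_counts(sub), target)
  expect_equal(sub$counts, t(sub$counts))
  expect_equal(sub$counts, subsample_counts(m, target, seed = 1)$counts)

  # marginal expectation original * target / total (3 SE band, 400 draws)
  cell <- c(2, 5)
  draws <- vapply(1:400, function(s) {
    subsample_counts(m, target, seed = s)$counts[cell[1], cell[2]]
  }, numeric(1))
  p <- target / tot
  mu <- m$counts[cell[1], cell[2]] * p
  se <- sqrt(m$counts[cell[1], cell[2]] * p * (1 - p)) / sqrt(400)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("log ratio map is zero for equal or proportional inputs", {
  m <- toy_matrix(6, seed = 9)
  expect_true(all(log_ratio_map(m, m) == 0))
  m2 <- contact_matrix(2 * m$counts)
  expect_true(all(abs(log_ratio_map(m2, m)) < 1e-12))
  a <- contact_matrix(matrix(c(4, 1, 1, 0), 2, 2))
  b <- contact_matrix(matrix(c(2, 1, 1, 2), 2, 2))
  s <- total_counts(b) / total_counts(a)
  expect_equal(log_ratio_map(a, b, pseudocount = 1),
               log2((a$counts * s + 1) / (b$counts + 1)))
})
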