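test_that("the loop kernel is standardized with an enriched centre", {
  for (size in c(9L, 17L)) {
    k <- loop_kernel(size)
    expect_equal(mean(k), 0, tolerance = 1e-12)
    expect_equal(stats::sd(as.vector(k)), 1, tolerance = 1e-12)
    h <- (size + 1) / 2
    border <- c(k[1, ], k[size, ], k[, 1], k[, size])
    expect_gt(k[h, h], mean(border))
  }
  expect_error(loop_kernel(10))
})

test_that("a window affinely matching the kernel scores exactly 1", {
  k <- loop_kernel(9)
  n <- 40
  # craft an O/E whose log(1 + O/E) window is an affine image of the kernel
  i0 <- 12; j0 <- 28
  oe <- matrix(1, n, n)
  ctr <- (9 + 1) / 2
  win <- expm1(0.05 * k + 0.2)  # log1p(win) = 0.05 k + 0.2
  oe[i0 + (1:9) - ctr, j0 + (1:9) - ctr] <- win
  m <- contact_matrix(matrix(10, n, n), bin_size = 10000L,
                      weights = rep(1, n))
  sc <- score_map(m, k, min_d = 1e5, max_d = 2.5e5, oe = oe)
  expect_equal(sc[i0, j0], 1, tolerance = 1e-9)
})

test_that("flat maps have undefined scores; scores equal a direct Pearson", {
  n <- 60
  flat <- contact_matrix(matrix(7, n, n), bin_size = 10000L)
  flat <- ice_balance(mask_low_coverage(flat, 0))
  k <- loop_kernel(9)
  sc <- score_map(flat, k, min_d = 5e4, max_d = 3e5)
  expect_true(all(is.na(sc)))

  m <- prep_matrix(toy_matrix(n, seed = 12), q = 0)
  sc <- score_map(m, k, min_d = 5e4, max_d = 3e5)
  L <- log1p(observed_over_expected(m))
  i <- 20; j <- 32
  oracle <- stats::cor(as.vector(k), as.vector(L[(i - 4):(i + 4),
                                                 (j - 4):(j + 4)]))
  expect_equal(sc[i, j], oracle)
})

test_that("scores are invariant under positive scaling of the counts", {
  m <- prep_matrix(toy_matrix(50, seed = 13), q = 0)
  k <- loop_kernel(9)
  s1 <- score_map(m, k, min_d = 5e4, max_d = 3e5)
  m2 <- contact_matrix(2 * m$counts, bin_size = 10000L)
  m2 <- ice_balance(mask_low_coverage(m2, 0))
  s2 <- score_map(m2, k, min_d = 5e4, max_d = 3e5)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("detection thresholds, suppresses neighbours and stays deterministic", {
  n <- 50
  sc <- matrix(NA_real_, n, n)
  sc[10, 20] <- 0.30
  sc[30, 45] <- 0.40
  calls <- detect_loops(sc, threshold = 0.35, bin_size = 10000L)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$bin1, 29)  # 0-based
  expect_equal(calls$score, 0.40)

  # two maxima one bin apart: the higher one survives
  sc2 <- matrix(NA_real_, n, n)
  sc2[10, 20] <- 0.6
  sc2[10, 21] <- 0.5
  sc2[40, 45] <- 0.7
  calls2 <- detect_loops(sc2, threshold = 0.35, min_separation = 3)
  expect_equal(nrow(calls2), 2)
  expect_setequal(calls2$score, c(0.6, 0.7))
  expect_identical(calls2, detect_loops(sc2, threshold = 0.35,
                                        min_separation = 3))
})

test_that("injected loops are recovered with high precision and recall", {
  loops <- data.frame(chrom = "chr1",
                      a1 = c(20L, 35L, 60L, 80L, 100L, 120L, 150L, 170L),
                      a2 = c(40L, 70L, 75L, 110L, 130L, 140L, 185L, 190L),
                      L = 5, w = 2)
  g <- genome_spec("chr1", 2e6, 10000L)
  k <- loop_kernel(17)
  tp <- fp <- fn <- 0
  for (s in 1:3) {
    p <- synthetic_hic_params(depth = 5e5, compartment_contrast = 0,
                              loops = loops, seed = s)
    m <- prep_matrix(simulate_contact_map(g, p)[[1]])
    sc <- score_map(m, k, min_d = 5e4, max_d = 1.5e6)
    calls <- detect_loops(sc, 0.35, bin_size = 10000L)
    matched <- rep(FALSE, nrow(loops))
    for (r in seq_len(nrow(calls))) {
      hit <- which(pmax(abs(loops$a1 - calls$bin1[r]),
                        abs(loops$a2 - calls$bin2[r])) <= 2)
      if (length(hit)) matched[hit[1]] <- TRUE else fp <- fp + 1
    }
    tp <- tp + sum(matched); fn <- fn + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tp / (tp + fp), 0.8)
})

test_that("quantification is deterministic and honours equal totals", {
  loops <- data.frame(chrom = "chr1", a1 = c(20L, 50L), a2 = c(40L, 80L),
                      L = 5, w = 2)
  g <- genome_spec("chr1", 1.2e6, 10000L)
  p <- synthetic_hic_params(depth = 2e5, compartment_contrast = 0,
                            loops = loops, seed = 9)
  m <- simulate_contact_map(g, p)[[1]]
  pos <- data.frame(bin1 = loops$a1, bin2 = loops$a2)
  q1 <- quantify_loops(pos, list(a = m, b = m), seed = 4,
                       kernel = loop_kernel(9), min_d = 5e4, max_d = 1e6)
  expect_equal(q1$a, q1$b)  # identical matrices, same totals
  q2 <- quantify_loops(pos, list(a = m, b = m), seed = 4,
                       kernel = loop_kernel(9), min_d = 5e4, max_d = 1e6)
  expect_identical(q1, q2)
  # position outside the scanning band is NA-flagged
  pos2 <- rbind(pos, data.frame(bin1 = 5L, bin2 = 6L))
  q3 <- quantify_loops(pos2, list(a = m), seed = 4, kernel = loop_kernel(9),
                       min_d = 5e4, max_d = 1e6)
  expect_true(is.na(q3$a[3]))
})

test_that("cluster classification separates intra, inter and distant loops", {
  cl <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                   cluster_id = "c1")
  loops <- data.frame(chrom = "chr1",
                      start1 = c(1200, 1200, 5000), end1 = c(1201, 1201, 5001),
                      start2 = c(1800, 5000, 6000), end2 = c(1801, 5001, 6001),
                      score = c(0.4, 0.2, 0.9))
  st <- classify_cluster_loops(loops, cl, max_length = 1e5)
  expect_equal(st[[1]]$intra, 0.4)
  expect_equal(st[[1]]$inter, 0.2)
  expect_equal(st[[1]]$ratio, 0.5)

  # the 500 kb length cap excludes long loops
  long <- data.frame(chrom = "chr1", start1 = 1200, end1 = 1201,
                     start2 = 6.2e5, end2 = 6.2e5 + 1, score = 0.8)
  st2 <- classify_cluster_loops(rbind(loops, long), cl, max_length = 5e5)
  expect_equal(st2[[1]]$inter, 0.2)

  over <- data.frame(chrom = "chr1", start = c(0, 500), end = c(1000, 1500))
  expect_error(classify_cluster_loops(loops, over), "overlap")
})

test_that("score reproducibility equals the rank-then-Pearson oracle", {
  a <- data.frame(loop_id = sprintf("l%02d", 1:50))
  withr::with_seed(3, {
    a$score <- stats::rnorm(50)
    b <- data.frame(loop_id = a$loop_id, score = a$score + stats::rnorm(50))
  })
  rho <- loop_score_correlation(a, b)
  expect_equal(rho, stats::cor(rank(a$score), rank(b$score)))
  expect_equal(loop_score_correlation(a, a), 1)
  rev <- data.frame(loop_id = a$loop_id, score = -a$score)
  expect_equal(loop_score_correlation(a, rev), -1)
  expect_error(loop_score_correlation(a[1:2, ], b[1:2, ]), "fewer than 3")
})
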