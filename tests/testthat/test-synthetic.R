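test_that("identical seeds give bit-identical draws; unit gains give identical pair", {
  g <- genome_spec("chr1", 8e5, 10000L)
  p <- synthetic_hic_params(depth = 5e4, seed = 3)
  m1 <- simulate_contact_map(g, p)
  m2 <- simulate_contact_map(g, p)
  expect_identical(m1[[1]]$counts, m2[[1]]$counts)

  pe <- perturbation_spec(data.frame(chrom = "chr1", start = 1e5, end = 3e5),
                          gamma_comp = 1, gamma_intra = 1, gamma_inter = 1)
  pair <- simulate_contact_pair(g, p, pe, seeds = c(3, 3))
  expect_identical(pair$untreated[[1]]$counts, pair$treated[[1]]$counts)
  # distinct derived seeds give a genuinely different replicate
  pair2 <- simulate_contact_pair(g, p, pe)
  expect_false(identical(pair2$untreated[[1]]$counts,
                         pair2$treated[[1]]$counts))
})

test_that("distance decay follows the configured power law", {
  # mean at distance d over mean at distance 2d-1 approaches ((2d)/(d+1))^alpha
  g <- genome_spec("chr1", 6e5, 10000L)  # 60 bins
  p0 <- synthetic_hic_params(decay_exponent = 1, depth = 2e5,
                             compartment_contrast = 0, seed = 1)
  d <- 5L
  num <- den <- 0
  for (s in 1:100) {
    p <- synthetic_hic_params(decay_exponent = 1, depth = 2e5,
                              compartment_contrast = 0, seed = s)
    m <- simulate_contact_map(g, p)[[1]]$counts
    i <- seq_len(60 - d)
    num <- num + mean(m[cbind(i, i + d)])
    i2 <- seq_len(60 - (2 * d - 1))
    den <- den + mean(m[cbind(i2, i2 + 2 * d - 1)])
  }
  ratio <- num / den
  expect_equal(ratio, (2 * d) / (d + 1), tolerance = 0.02)
})

test_that("an injected loop enriches its anchor cell by 1 + L", {
  g <- genome_spec("chr1", 6e5, 10000L)
  loops <- data.frame(chrom = "chr1", a1 = 15L, a2 = 40L, L = 5, w = 2)
  anchor <- c()
  background <- c()
  for (s in 1:60) {
    p <- synthetic_hic_params(decay_exponent = 1, depth = 3e5,
                              compartment_contrast = 0, loops = loops,
                              seed = s)
    m <- simulate_contact_map(g, p)[[1]]$counts
    anchor <- c(anchor, m[16, 41])
    d <- 25L
    i <- seq_len(60 - d)
    cells <- m[cbind(i, i + d)]
    background <- c(background, mean(cells[abs(i - 16) > 8]))
  }
  expect_equal(mean(anchor) / mean(background), 6, tolerance = 0.1)
})

test_that("total counts concentrate around the configured depth", {
  g <- genome_spec("chr1", 8e5, 10000L)
  for (s in 1:5) {
    p <- synthetic_hic_params(depth = 1e5, compartment_contrast = 0, seed = s)
    m <- simulate_contact_map(g, p)[[1]]
    expect_lt(abs(total_counts(m) - 1e5), 3 * sqrt(1e5))
  }
})

test_that("negative means are rejected up front", {
  g <- genome_spec("chr1", 4e5, 10000L)
  p <- synthetic_hic_params(compartment_contrast = 1.2, seed = 1)
  expect_error(simulate_contact_map(g, p), "negative")
})

test_that("peak placement respects clusters, genes and crowding", {
  g <- genome_spec("chr1", 1e6, 10000L)
  cl <- data.frame(chrom = "chr1", start = 1e5, end = 2e5,
                   cluster_id = "c1")
  pk <- simulate_peaks(g, cl, n_per_cluster = 5, peak_width = 1000,
                       seed = 4)
  expect_equal(nrow(pk), 5)
  expect_true(all(pk$start >= 1e5 & pk$end <= 2e5))
  o <- pk[order(pk$start), ]
  expect_true(all(o$start[-1] >= o$end[-5]))
  # reproducible
  expect_equal(simulate_peaks(g, cl, n_per_cluster = 5, peak_width = 1000,
                              seed = 4), pk)

  # gene body covering the whole cluster leaves no space
  genes <- data.frame(chrom = "chr1", start = 9e4, end = 2.1e5)
  expect_error(simulate_peaks(g, cl, genes = genes, n_per_cluster = 1,
                              peak_width = 1000, seed = 1),
               "crowded")
  # peaks avoid partial gene cover
  genes2 <- data.frame(chrom = "chr1", start = 1.4e5, end = 1.6e5)
  pk2 <- simulate_peaks(g, cl, genes = genes2, n_per_cluster = 4,
                        peak_width = 1000, seed = 5)
  expect_false(any(pk2$start < 1.6e5 & pk2$end > 1.4e5))

  expect_equal(nrow(simulate_peaks(g, cl, n_per_cluster = 0, seed = 1)), 0)
})

test_that("differential tables encode the class structure", {
  truth <- make_truth_genes(n_genes = 200, seed = 2)
  tabs <- simulate_differential_tables(truth, sd = 0, seed = 3)
  ext <- truth$induced_a & truth$magnitude == "extreme"
  expect_true(all(tabs$rna_a$log2FC[ext] == 6))
  mod <- truth$induced_a & truth$magnitude == "moderate"
  expect_true(all(tabs$rna_a$log2FC[mod] == 3))
  expect_true(all(tabs$rna_a$padj[truth$induced_a] <= 0.01))
  expect_true(all(tabs$atac_ko$log2FC[truth$isgf3_dependent] == -3))

  # all-null truth propagates to zero significant calls downstream
  null_truth <- truth
  null_truth$induced_a <- null_truth$induced_b <- FALSE
  null_truth$isgf3_dependent <- null_truth$homeostatic <- FALSE
  null_truth$magnitude <- "none"
  tabs0 <- simulate_differential_tables(null_truth, sd = 0, seed = 4)
  cls <- classify_type_specific(tabs0$rna_a, tabs0$rna_b)
  expect_true(all(cls$class == "none"))

  expect_error(simulate_differential_tables(truth, effect = list(extreme = 6),
                                            seed = 1),
               "missing effect")
})

test_that("cluster membership of injected loops is classified correctly", {
  cl <- data.frame(chrom = "chr1", start = c(1e5, 3e5), end = c(2e5, 4e5))
  loops <- data.frame(chrom = "chr1",
                      a1 = c(11L, 12L, 50L, 15L), a2 = c(18L, 40L, 60L, 35L),
                      L = 5, w = 2)
  out <- ifn3d:::classify_loop_truth(loops, cl, 10000L)
  # anchors in two different clusters count as inter, not intra
  expect_equal(out$class, c("intra", "inter", "background", "inter"))
})
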