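test_that("type-specific classification follows the significance rules", {
  tbl_a <- data.frame(id = c("g1", "g2", "g3", "g4"),
                      log2FC = c(2, 2, 1.5, 0.2),
                      padj = c(0.01, 0.2, 0.001, 0.9))
  tbl_b <- data.frame(id = c("g1", "g2", "g3", "g4"),
                      log2FC = c(0.5, 0.5, 2, 0.1),
                      padj = c(0.5, 0.5, 0.01, 0.9))
  cls <- classify_type_specific(tbl_a, tbl_b)
  expect_equal(cls$class[cls$gene_id == "g1"], "A_specific")
  expect_equal(cls$class[cls$gene_id == "g2"], "none")  # padj_a too large
  expect_equal(cls$class[cls$gene_id == "g3"], "shared")
  expect_equal(cls$class[cls$gene_id == "g4"], "none")

  # genes missing from one table are excluded and counted
  cls2 <- classify_type_specific(tbl_a, tbl_b[1:3, ])
  expect_equal(nrow(cls2), 3)
  expect_equal(attr(cls2, "n_excluded"), 1)

  # order-independence and idempotence
  cls3 <- classify_type_specific(tbl_a[4:1, ], tbl_b[c(3, 1, 4, 2), ])
  expect_equal(cls3[order(cls3$gene_id), ]$class,
               cls[order(cls$gene_id), ]$class)
})

test_that("induced-group selection matches strata rules and a sort oracle", {
  tbl <- data.frame(id = c("a", "b", "c", "d"),
                    log2FC = c(6, 3, 0.5, 7),
                    padj = c(0.01, 0.01, 0.01, 0.5))
  st <- select_induced_groups(tbl, "strata")
  expect_equal(st$extreme, "a")  # d not significant
  expect_equal(st$moderate, "b")

  withr::with_seed(6, {
    big <- data.frame(id = sprintf("g%03d", 1:300),
                      log2FC = stats::runif(300, 0, 8),
                      padj = stats::runif(300, 0, 0.2))
  })
  top <- select_induced_groups(big, "top200", n_top = 50)
  sig <- big[big$padj <= 0.05 & big$log2FC >= 1, ]
  oracle <- sig$id[order(-sig$log2FC, sig$id)]
  expect_equal(top, utils::head(oracle, 50))

  expect_warning(select_induced_groups(tbl, "top200"), "available")
  expect_error(select_induced_groups(tbl[0, ], "top200"), "empty")
})

test_that("peak-to-gene annotation uses the stranded TSS and deterministic ties", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1000, 2000, 10000),
                      end = c(1500, 5000, 12000),
                      gene_id = c("gA", "gB", "gC"),
                      strand = c("+", "-", "+"))
  peaks <- data.frame(chrom = "chr1",
                      start = c(1400, 4900, 7490),
                      end = c(1600, 5100, 7510),
                      peak_id = c("p1", "p2", "p3"))
  ann <- annotate_peaks_to_genes(peaks, genes)
  expect_equal(ann$gene_id[1], "gA")       # mid 1500, nearest TSS 1000
  expect_equal(ann$gene_id[2], "gB")       # minus strand: TSS = 5000
  expect_equal(ann$gene_id[3], "gB")       # equidistant 5000/10000: smaller id
  # no gene on the chromosome: unassigned
  ann2 <- annotate_peaks_to_genes(
    data.frame(chrom = "chr9", start = 1, end = 10, peak_id = "px"), genes)
  expect_true(is.na(ann2$gene_id))
})

test_that("accessibility-dependence rules mark red, blue and homeostatic sets", {
  rna <- list(
    a = data.frame(id = c("g1", "g2", "g3"), log2FC = c(3, 3, 0.2),
                   padj = c(0.001, 0.001, 0.5)),
    b = data.frame(id = c("g1", "g2", "g3"), log2FC = c(0, 0, 0),
                   padj = c(1, 1, 1)),
    ko = data.frame(id = c("g1", "g2", "g3"), log2FC = c(0, 0, -2),
                    padj = c(1, 1, 0.01)))
  atac <- list(
    a = data.frame(id = c("k1", "k2", "k3"), log2FC = c(1.5, 1.5, 0),
                   padj = c(0.01, 0.01, 1)),
    b = data.frame(id = c("k1", "k2", "k3"), log2FC = 0, padj = 1),
    ko = data.frame(id = c("k1", "k2", "k3"), log2FC = c(-2, -0.5, -2),
                    padj = c(0.01, 0.01, 0.01)))
  annot <- data.frame(peak_id = c("k1", "k2", "k3"),
                      gene_id = c("g1", "g2", "g3"))
  out <- classify_accessibility_dependence(rna, atac, annot)
  cls <- out$classification
  expect_true(cls$red_a[cls$gene_id == "g1"])
  expect_true(cls$blue_a[cls$gene_id == "g1"])   # ko peak at -2
  expect_true(cls$red_a[cls$gene_id == "g2"])
  expect_false(cls$blue_a[cls$gene_id == "g2"])  # ko peak only -0.5
  expect_true(cls$homeostatic[cls$gene_id == "g3"])
  expect_equal(unname(out$contingency["IFN_A", ]), c(1, 1))

  expect_error(classify_accessibility_dependence(rna[c("a", "b")], atac,
                                                 annot),
               "missing contrast")
})

test_that("chi-squared handles the uniform, hand-computed and degenerate cases", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p, 1)

  t2 <- matrix(c(20, 10, 10, 20), 2, 2)
  r <- chi_square_2x2(t2)
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(r$p, pchisq(20 / 3, 1, lower.tail = FALSE))

  # invariant under swapping both rows and both columns
  swapped <- t2[2:1, 2:1]
  expect_equal(chi_square_2x2(swapped)$chi2, r$chi2)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("truth-labelled tables are recovered essentially perfectly at low noise", {
  truth <- make_truth_genes(n_genes = 300, seed = 7)
  tabs <- simulate_differential_tables(truth, sd = 0.1, seed = 8)
  cls <- classify_type_specific(tabs$rna_a, tabs$rna_b)
  m <- merge(cls, truth, by = "gene_id")
  expect_gte(mean(m$class == m$class_ab), 0.99)

  st <- select_induced_groups(tabs$rna_a, "strata")
  truth_ext <- truth$gene_id[truth$induced_a & truth$magnitude == "extreme"]
  truth_mod <- truth$gene_id[truth$induced_a & truth$magnitude == "moderate"]
  agree <- function(x, y) {
    length(intersect(x, y)) / max(length(union(x, y)), 1)
  }
  expect_gte(agree(st$extreme, truth_ext), 0.99)
  expect_gte(agree(st$moderate, truth_mod), 0.99)
})
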