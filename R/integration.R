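#' Classify genes as IFN-type-specific, shared, or neither
#'
#' A gene is A-specific when significantly up-regulated under stimulus A
#' (`log2FC >= fc_thresh` and `padj <= padj_thresh`) but not induced under
#' stimulus B (`log2FC < fc_thresh`); symmetrically for B-specific. Genes
#' significantly up in both are `shared`; everything else is `none`. Genes
#' missing from either table are excluded (count returned as an attribute).
#'
#' @param tbl_a,tbl_b differential tables (`id`, `log2FC`, `padj`) for the
#'   two stimuli.
#' @param fc_thresh,padj_thresh significance thresholds (defaults 1, 0.05).
#' @return data frame `gene_id`, `class`; attribute `n_excluded`.
#' @export
classify_type_specific <- function(tbl_a, tbl_b, fc_thresh = 1,
                                   padj_thresh = 0.05) {
  m <- merge(tbl_a[, c("id", "log2FC", "padj")],
             tbl_b[, c("id", "log2FC", "padj")],
             by = "id", suffixes = c("_a", "_b"))
  n_excluded <- length(union(tbl_a$id, tbl_b$id)) - nrow(m)
  sig_a <- m$log2FC_a >= fc_thresh & m$padj_a <= padj_thresh
  sig_b <- m$log2FC_b >= fc_thresh & m$padj_b <= padj_thresh
  class <- ifelse(sig_a & sig_b, "shared",
           ifelse(sig_a & m$log2FC_b < fc_thresh, "A_specific",
           ifelse(sig_b & m$log2FC_a < fc_thresh, "B_specific", "none")))
  out <- data.frame(gene_id = m$id, class = class)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Select induced gene groups: top-200 or induction strata
#'
#' `mode = "top200"`: among genes with `padj <= 0.05` and `log2FC >= 1`, the
#' 200 with the largest log2FC (ties broken by gene id; fewer than 200
#' available yields all of them with a warning). `mode = "strata"`: the
#' extreme stratum (`log2FC > 5`) and the moderate stratum
#' (`1 <= log2FC <= 5`), both requiring `padj <= 0.05`.
#'
#' @param tbl differential table (`id`, `log2FC`, `padj`).
#' @param mode `"top200"` or `"strata"`.
#' @param n_top group size for `top200`.
#' @return for `top200` a character vector of gene ids; for `strata` a list
#'   with `extreme` and `moderate` id vectors.
#' @export
select_induced_groups <- function(tbl, mode = c("top200", "strata"),
                                  n_top = 200L) {
  mode <- match.arg(mode)
  if (nrow(tbl) == 0) stop("empty differential table")
  sig <- tbl[tbl$padj <= 0.05 & tbl$log2FC >= 1, , drop = FALSE]
  if (mode == "top200") {
    sig <- sig[order(-sig$log2FC, sig$id), , drop = FALSE]
    if (nrow(sig) < n_top) {
      warning(sprintf("only %d significant genes available (requested %d)",
                      nrow(sig), n_top))
    }
    utils::head(sig$id, n_top)
  } else {
    list(extreme = tbl$id[tbl$padj <= 0.05 & tbl$log2FC > 5],
         moderate = tbl$id[tbl$padj <= 0.05 & tbl$log2FC >= 1 &
                             tbl$log2FC <= 5])
  }
}

#' Annotate peaks to the gene with the nearest TSS
#'
#' The TSS is the gene start on the plus strand and the gene end on the
#' minus strand; each peak is assigned to the gene whose TSS is nearest its
#' midpoint, with ties broken deterministically by the smaller gene id.
#'
#' @param peaks data frame `chrom, start, end, peak_id`.
#' @param genes data frame `chrom, start, end, gene_id, strand`.
#' @return data frame `peak_id, gene_id, distance` (`gene_id` NA when the
#'   peak's chromosome carries no gene).
#' @export
annotate_peaks_to_genes <- function(peaks, genes) {
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  out <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    distance = NA_real_)
  for (k in seq_len(nrow(peaks))) {
    g <- which(genes$chrom == peaks$chrom[k])
    if (length(g) == 0) next
    mid <- interval_midpoint(peaks$start[k], peaks$end[k])
    dist <- abs(tss[g] - mid)
    ord <- order(dist, genes$gene_id[g])
    out$gene_id[k] <- genes$gene_id[g[ord[1]]]
    out$distance[k] <- dist[ord[1]]
  }
  out
}

#' ISGF3-dependence classification of induced accessibility
#'
#' For each IFN type: the `red` set contains genes significantly RNA-up
#' under stimulation with at least one annotated peak significantly ATAC-up
#' under the same stimulation; the `blue` subset additionally has a peak
#' with significantly decreased accessibility in the Irf9 knockout
#' (ISGF3-dependent). The homeostatic set pairs knockout RNA-down genes with
#' knockout ATAC-down peaks. The 2x2 contingency table counts, per IFN type,
#' ISGF3-dependent (blue) versus independent (red but not blue) loci.
#'
#' @param rna named list of differential tables `a`, `b`, `ko` keyed by gene
#'   id (`ko` = knockout vs wildtype at rest).
#' @param atac named list of peak-level tables `a`, `b`, `ko`, each with
#'   `id`, `log2FC`, `padj`.
#' @param annot peak-to-gene map (`peak_id`, `gene_id`), e.g. from
#'   [annotate_peaks_to_genes()].
#' @param fc_thresh,padj_thresh significance thresholds.
#' @param quantifier how peaks aggregate to a gene: `"any"` (default) or
#'   `"all"` annotated peak(s) must pass.
#' @return list with `classification` (per gene and IFN type: `red`, `blue`,
#'   `homeostatic`, and a four-way `category` label) and `contingency`
#'   (2x2 matrix, rows IFN types, columns dependent/independent).
#' @export
classify_accessibility_dependence <- function(rna, atac, annot,
                                              fc_thresh = 1,
                                              padj_thresh = 0.05,
                                              quantifier = c("any", "all")) {
  quantifier <- match.arg(quantifier)
  for (nm in c("a", "b", "ko")) {
    if (is.null(rna[[nm]]) || is.null(atac[[nm]])) {
      stop("missing contrast table: ", nm)
    }
  }
  agg <- if (quantifier == "any") any else all
  gene_peak_flag <- function(tbl, up) {
    sig <- if (up) tbl$log2FC >= fc_thresh & tbl$padj <= padj_thresh else
      tbl$log2FC <= -fc_thresh & tbl$padj <= padj_thresh
    hit <- merge(data.frame(peak_id = tbl$id, sig = sig), annot,
                 by = "peak_id")
    flags <- tapply(hit$sig, hit$gene_id, agg)
    names(flags)[flags]
  }
  rna_flag <- function(tbl, up) {
    if (up) tbl$id[tbl$log2FC >= fc_thresh & tbl$padj <= padj_thresh] else
      tbl$id[tbl$log2FC <= -fc_thresh & tbl$padj <= padj_thresh]
  }
  atac_up_a <- gene_peak_flag(atac$a, up = TRUE)
  atac_up_b <- gene_peak_flag(atac$b, up = TRUE)
  atac_dn_ko <- gene_peak_flag(atac$ko, up = FALSE)
  genes <- sort(unique(c(rna$a$id, rna$b$id, rna$ko$id)))
  red_a <- genes %in% rna_flag(rna$a, TRUE) & genes %in% atac_up_a
  red_b <- genes %in% rna_flag(rna$b, TRUE) & genes %in% atac_up_b
  dn_ko <- genes %in% atac_dn_ko
  blue_a <- red_a & dn_ko
  blue_b <- red_b & dn_ko
  homeo <- genes %in% rna_flag(rna$ko, FALSE) & dn_ko
  category <- ifelse((blue_a | blue_b) & homeo,
                     "homeostatic_and_induced_ISGF3_dependent",
              ifelse(blue_a | blue_b, "induced_ISGF3_dependent",
              ifelse(red_a | red_b, "induced_ISGF3_independent",
              ifelse(homeo, "homeostatic_ISGF3_dependent", "none"))))
  classification <- data.frame(gene_id = genes,
                               red_a = red_a, blue_a = blue_a,
                               red_b = red_b, blue_b = blue_b,
                               homeostatic = homeo, category = category)
  contingency <- matrix(c(sum(blue_a), sum(red_a & !blue_a),
                          sum(blue_b), sum(red_b & !blue_b)),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("IFN_A", "IFN_B"),
                                        c("ISGF3_dependent",
                                          "ISGF3_independent")))
  list(classification = classification, contingency = contingency)
}

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' One degree of freedom, Yates continuity correction off by default; the
#' p-value comes from the chi-squared survival function.
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @param yates apply the continuity correction.
#' @return list with `chi2`, `p`.
#' @export
chi_square_2x2 <- function(tbl, yates = FALSE) {
  tbl <- as.matrix(tbl)
  stopifnot(all(dim(tbl) == 2), all(tbl >= 0), sum(tbl) > 0)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stop("zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(tbl, correct = yates))
  list(chi2 = unname(res$statistic), p = res$p.value)
}
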