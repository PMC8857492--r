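#' Default pipeline configuration
#'
#' Analysis defaults in one place: 40 kb compartment bins with 1 Mb control
#' offsets, loop score threshold 0.35, 500 kb maximum loop length, 10 Mb
#' loop scanning ceiling, 1 Mb SCC scanning distance, log2FC thresholds 1
#' and 5 with padj 0.05, top-200 induced genes — plus the synthetic study
#' conditions: a 10 Mb chromosome at 40 kb resolution with five 560 kb ISG
#' clusters in A blocks at merged-replicate coverage (4e6 contacts) for the
#' compartment analyses, and a 2 Mb chromosome at 10 kb resolution with
#' three 300 kb clusters, injected dot loops (L = 5, w = 2 bins) and
#' 5e5 contacts for the loop and regulatory-interaction analyses.
#'
#' @param seed master RNG seed.
#' @return named list of parameters.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # compartment-scale synthetic conditions (40 kb)
    comp_n_bins = 250L, comp_bin_size = 40000L, comp_depth = 4e6,
    decay_exponent = 1, compartment_contrast = 0.4, block_width = 20L,
    comp_cluster_starts = c(43L, 83L, 123L, 163L, 203L),
    comp_cluster_width = 14L, gamma_comp = 1.5,
    # loop-scale synthetic conditions (10 kb)
    loop_n_bins = 200L, loop_bin_size = 10000L, loop_depth = 5e5,
    loop_cluster_starts = c(20L, 85L, 146L), loop_cluster_width = 30L,
    loop_L = 5, loop_w = 2, gamma_intra = 2, gamma_inter = 0.5,
    # analysis parameters
    mask_quantile = 0.02, control_offset = 1e6,
    loop_threshold = 0.35, loop_max_length = 5e5,
    loop_min_d = 5e4, loop_max_d = 1e7, kernel_size = 17L,
    scc_h = 1L, scc_max_distance = 1e6,
    saddle_quantiles = 10L, corner_fraction = 0.2,
    fc_thresh = 1, fc_extreme = 5, padj_thresh = 0.05, n_top = 200L,
    n_genes = 400L
  )
}

# cluster table for the compartment-scale genome
comp_clusters <- function(cfg) {
  data.frame(
    chrom = "chr1",
    start = cfg$comp_cluster_starts * cfg$comp_bin_size,
    end = (cfg$comp_cluster_starts + cfg$comp_cluster_width) *
      cfg$comp_bin_size,
    cluster_id = sprintf("isg_cluster_%d", seq_along(cfg$comp_cluster_starts)))
}

# cluster table for the loop-scale genome
loop_clusters <- function(cfg) {
  data.frame(
    chrom = "chr1",
    start = cfg$loop_cluster_starts * cfg$loop_bin_size,
    end = (cfg$loop_cluster_starts + cfg$loop_cluster_width) *
      cfg$loop_bin_size,
    cluster_id = sprintf("isg_cluster_%d", seq_along(cfg$loop_cluster_starts)))
}

#' Deterministic intra- and inter-cluster loop layout
#'
#' Places `n_intra` loops with both anchors inside each cluster and
#' `n_inter` loops connecting a cluster anchor to a flanking position,
#' within the matrix bounds. Used as the injected loop set of the synthetic
#' loop-scale study conditions.
#'
#' @param clusters cluster data frame (`chrom`, `start`, `end`).
#' @param bin_size bin width in bp.
#' @param n_bins_chrom bins on the chromosome.
#' @param n_intra,n_inter loops per cluster and class.
#' @param L,w enrichment and width (bins) of each injected loop.
#' @return loop data frame for [synthetic_hic_params()].
#' @export
synthetic_cluster_loops <- function(clusters, bin_size, n_bins_chrom,
                                    n_intra = 3L, n_inter = 3L, L = 5,
                                    w = 2) {
  rows <- list()
  for (k in seq_len(nrow(clusters))) {
    b0 <- floor(clusters$start[k] / bin_size)
    b1 <- ceiling(clusters$end[k] / bin_size) - 1L
    width <- b1 - b0 + 1L
    i_a1 <- b0 + round(width * c(0.08, 0.18, 0.3))[seq_len(n_intra)]
    i_a2 <- b0 + round(width * c(0.5, 0.7, 0.9))[seq_len(n_intra)]
    for (q in seq_len(n_intra)) {
      rows[[length(rows) + 1]] <- data.frame(chrom = clusters$chrom[k],
                                             a1 = i_a1[q], a2 = i_a2[q],
                                             L = L, w = w)
    }
    # inter anchors reach into the downstream flank (upstream if no room)
    off <- round(width * c(1.2, 1.4, 1.6))[seq_len(n_inter)]
    for (q in seq_len(n_inter)) {
      a1 <- b0 + round(width * 0.25 * q)
      a2 <- b0 + off[q]
      if (a2 >= n_bins_chrom) {
        a2 <- a1 + 3L
        a1 <- b0 - off[q]
        if (a1 < 0) next
      }
      rows[[length(rows) + 1]] <- data.frame(chrom = clusters$chrom[k],
                                             a1 = a1, a2 = a2, L = L, w = w)
    }
  }
  unique(do.call(rbind, rows))
}

#' Run the full synthetic end-to-end analysis
#'
#' Simulates the configured paired untreated/treated study and runs every
#' analysis stage: replicate similarity (SCC), compartment calling with
#' saddle strength and region-versus-control delta-PC1 plus the rank-sum
#' test; fusion-map loop detection with coverage-equalized per-condition
#' quantification and inter/intra-cluster ratios; the distance-matched
#' control-pair interaction-strength test on accessible regulatory regions;
#' and the differential-table classification rules with the 2x2 chi-squared
#' comparison. Writes all tables plus a manifest (parameters, seed, output
#' checksums) to `outdir`; identical config and seed give identical
#' checksums.
#'
#' @param config a [default_config()]-style list.
#' @param outdir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config

  ## --- compartment stage (40 kb) -------------------------------------
  gc_ <- genome_spec("chr1", cfg$comp_n_bins * cfg$comp_bin_size,
                     cfg$comp_bin_size)
  ccl <- comp_clusters(cfg)
  params_c <- synthetic_hic_params(cfg$decay_exponent, cfg$comp_depth,
                                   compartment_contrast =
                                     cfg$compartment_contrast,
                                   block_width = cfg$block_width,
                                   seed = cfg$seed)
  sim_c <- simulate_contact_pair(gc_, params_c,
                                 perturbation_spec(ccl,
                                                   gamma_comp = cfg$gamma_comp))
  mu <- sim_c$untreated[[1]]; mt <- sim_c$treated[[1]]
  write_contact_matrix(mu, file.path(outdir, "comp_untreated_chr1.tsv"))
  write_contact_matrix(mt, file.path(outdir, "comp_treated_chr1.tsv"))
  sim_scc <- scc(mu, mt, h = cfg$scc_h, max_distance = cfg$scc_max_distance)
  prep <- function(m) ice_balance(mask_low_coverage(m, cfg$mask_quantile))
  bu <- prep(mu); bt <- prep(mt)
  activity <- make_compartment_profile(cfg$comp_n_bins, cfg$block_width)
  cu <- compute_compartment_track(bu, activity)
  ct <- compute_compartment_track(bt, activity)
  write_bedgraph_track(cu$pc1, "chr1", cfg$comp_bin_size,
                       file.path(outdir, "pc1_untreated.bedgraph"))
  write_bedgraph_track(ct$pc1, "chr1", cfg$comp_bin_size,
                       file.path(outdir, "pc1_treated.bedgraph"))
  sad_u <- saddle_strength(bu, cu$pc1, cfg$saddle_quantiles,
                           cfg$corner_fraction)
  sad_t <- saddle_strength(bt, ct$pc1, cfg$saddle_quantiles,
                           cfg$corner_fraction)
  dstat <- delta_pc1_regions(ct$pc1, cu$pc1, ccl,
                             bin_size = cfg$comp_bin_size,
                             chrom_length = gc_$lengths[1],
                             control_offset = cfg$control_offset)
  utils::write.table(dstat, file.path(outdir, "delta_pc1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  drs <- rank_sum_test(dstat$mean_delta,
                       c(dstat$control_up, dstat$control_down))

  ## --- loop stage (10 kb) --------------------------------------------
  gl <- genome_spec("chr1", cfg$loop_n_bins * cfg$loop_bin_size,
                    cfg$loop_bin_size)
  lcl <- loop_clusters(cfg)
  loops <- synthetic_cluster_loops(lcl, cfg$loop_bin_size, cfg$loop_n_bins,
                                   L = cfg$loop_L, w = cfg$loop_w)
  params_l <- synthetic_hic_params(cfg$decay_exponent, cfg$loop_depth,
                                   compartment_contrast = 0,
                                   loops = loops, seed = cfg$seed + 101L)
  sim_l <- simulate_contact_pair(gl, params_l,
                                 perturbation_spec(lcl,
                                                   gamma_intra = cfg$gamma_intra,
                                                   gamma_inter = cfg$gamma_inter))
  lu <- sim_l$untreated[[1]]; lt <- sim_l$treated[[1]]
  kernel <- loop_kernel(cfg$kernel_size)
  fusion <- merge_matrices(list(lu, lt))
  fb <- ice_balance(mask_low_coverage(fusion, cfg$mask_quantile))
  smap <- score_map(fb, kernel, min_d = cfg$loop_min_d,
                    max_d = cfg$loop_max_d)
  calls <- detect_loops(smap, cfg$loop_threshold, chrom = "chr1",
                        bin_size = cfg$loop_bin_size)
  write_bedpe(calls, file.path(outdir, "loops_fusion.bedpe"))
  ratios <- NULL
  if (nrow(calls) > 0) {
    qt <- quantify_loops(calls, list(untreated = lu, treated = lt),
                         kernel = kernel, seed = cfg$seed,
                         min_d = cfg$loop_min_d, max_d = cfg$loop_max_d,
                         mask_quantile = cfg$mask_quantile)
    utils::write.table(qt, file.path(outdir, "loop_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    qcalls <- cbind(calls[, c("chrom", "start1", "end1", "start2", "end2")],
                    untreated = qt$untreated, treated = qt$treated)
    ratios <- lapply(c("untreated", "treated"), function(cond) {
      stats_l <- classify_cluster_loops(qcalls, lcl,
                                        max_length = cfg$loop_max_length,
                                        score_col = cond)
      vapply(stats_l, function(x) x$ratio, numeric(1))
    })
    names(ratios) <- c("untreated", "treated")
  }

  ## --- regulatory interactions on the treated loop-scale map ---------
  peaks <- simulate_peaks(gl, lcl, n_per_cluster = 4L,
                          seed = cfg$seed + 7L)
  reg <- select_regulatory_peaks(peaks, lcl)
  write_bed(reg, file.path(outdir, "regulatory_peaks.bed"))
  bt_l <- ice_balance(mask_low_coverage(lt, 0))
  strengths <- cluster_pair_strengths(reg, bt_l, gl$lengths[1])
  utils::write.table(strengths, file.path(outdir, "pair_strengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- paired_enrichment_test(strengths)

  ## --- differential-table integration --------------------------------
  truth <- make_truth_genes(n_genes = cfg$n_genes, seed = cfg$seed + 11L)
  tabs <- simulate_differential_tables(truth, seed = cfg$seed + 13L)
  for (nm in names(tabs)) {
    write_diff_table(tabs[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }
  type_cls <- classify_type_specific(tabs$rna_a, tabs$rna_b,
                                     cfg$fc_thresh, cfg$padj_thresh)
  utils::write.table(type_cls, file.path(outdir, "type_specific.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  annot <- data.frame(peak_id = tabs$atac_a$id, gene_id = tabs$atac_a$gene_id)
  acc <- classify_accessibility_dependence(
    list(a = tabs$rna_a, b = tabs$rna_b, ko = tabs$rna_ko),
    list(a = tabs$atac_a, b = tabs$atac_b, ko = tabs$atac_ko), annot,
    fc_thresh = cfg$fc_thresh, padj_thresh = cfg$padj_thresh)
  utils::write.table(acc$classification,
                     file.path(outdir, "accessibility_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chisq <- tryCatch(chi_square_2x2(acc$contingency),
                    error = function(e) list(chi2 = NA_real_, p = NA_real_))

  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  checks <- tools::md5sum(files)
  names(checks) <- basename(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ifn3d")),
    seed = cfg$seed, config = cfg,
    summary = list(
      scc = sim_scc$scc,
      phase_correlation = c(untreated = cu$phase_correlation,
                            treated = ct$phase_correlation),
      saddle_strength = c(untreated = sad_u$strength,
                          treated = sad_t$strength),
      delta_pc1_rank_sum_p = drs$p,
      n_loops = nrow(calls),
      cluster_ratios = ratios,
      pair_test = enr[c("n", "p", "median_real", "median_control")],
      contingency = as.vector(acc$contingency),
      chisq_p = chisq$p),
    checksums = as.list(checks))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
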