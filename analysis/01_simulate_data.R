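#!/usr/bin/env Rscript
# Stage 1: generate the synthetic paired-condition study.
#
# Two scales mirror the two arms of the analysis:
#  - a 10 Mb chromosome at 40 kb resolution with five 560 kb ISG-like
#    clusters inside A compartment blocks, two replicates per condition at
#    2e6 contacts each (compartment arm; treated condition gains 1.5x
#    compartment contrast inside clusters);
#  - a 2 Mb chromosome at 10 kb resolution with three 300 kb clusters and
#    injected dot loops (L = 5, w = 2 bins) at 5e5 contacts (loop arm;
#    treated condition doubles intra-cluster and halves inter-cluster loop
#    strength), plus accessible regulatory peaks inside the clusters;
#  - truth-labelled differential RNA/ATAC tables for 400 genes.
suppressPackageStartupMessages(library(ifn3d))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config(seed)

## compartment arm: two replicates per condition, merged downstream
gc_ <- genome_spec("chr1", cfg$comp_n_bins * cfg$comp_bin_size,
                   cfg$comp_bin_size)
ccl <- data.frame(chrom = "chr1",
                  start = cfg$comp_cluster_starts * cfg$comp_bin_size,
                  end = (cfg$comp_cluster_starts + cfg$comp_cluster_width) *
                    cfg$comp_bin_size,
                  cluster_id = sprintf("isg_cluster_%d",
                                       seq_along(cfg$comp_cluster_starts)))
params <- synthetic_hic_params(cfg$decay_exponent, cfg$comp_depth / 2,
                               compartment_contrast =
                                 cfg$compartment_contrast,
                               block_width = cfg$block_width, seed = seed)
perturb <- perturbation_spec(ccl, gamma_comp = cfg$gamma_comp)
for (rep in 1:2) {
  pair <- simulate_contact_pair(gc_, params, perturb,
                                seeds = c(seed + 10L * rep,
                                          seed + 10L * rep + 5L))
  write_contact_matrix(pair$untreated[[1]],
                       file.path(out, sprintf("comp_untreated_rep%d.tsv",
                                              rep)))
  write_contact_matrix(pair$treated[[1]],
                       file.path(out, sprintf("comp_treated_rep%d.tsv", rep)))
}
write_bed(transform(ccl, name = cluster_id), file.path(out, "clusters_40kb.bed"))
write_bedgraph_track(make_compartment_profile(cfg$comp_n_bins,
                                              cfg$block_width),
                     "chr1", cfg$comp_bin_size,
                     file.path(out, "activity_40kb.bedgraph"))

## loop arm: clusters, injected loops, regulatory peaks
gl <- genome_spec("chr1", cfg$loop_n_bins * cfg$loop_bin_size,
                  cfg$loop_bin_size)
lcl <- data.frame(chrom = "chr1",
                  start = cfg$loop_cluster_starts * cfg$loop_bin_size,
                  end = (cfg$loop_cluster_starts + cfg$loop_cluster_width) *
                    cfg$loop_bin_size,
                  cluster_id = sprintf("isg_cluster_%d",
                                       seq_along(cfg$loop_cluster_starts)))
loops <- synthetic_cluster_loops(lcl, cfg$loop_bin_size, cfg$loop_n_bins,
                                 L = cfg$loop_L, w = cfg$loop_w)
lp <- synthetic_hic_params(cfg$decay_exponent, cfg$loop_depth,
                           compartment_contrast = 0, loops = loops,
                           seed = seed + 101L)
lpe <- perturbation_spec(lcl, gamma_intra = cfg$gamma_intra,
                         gamma_inter = cfg$gamma_inter)
sim <- simulate_contact_pair(gl, lp, lpe)
write_contact_matrix(sim$untreated[[1]],
                     file.path(out, "loop_untreated.tsv"))
write_contact_matrix(sim$treated[[1]], file.path(out, "loop_treated.tsv"))
write.table(sim$truth$loops, file.path(out, "loop_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_bed(transform(lcl, name = cluster_id), file.path(out, "clusters_10kb.bed"))

peaks <- simulate_peaks(gl, lcl, n_per_cluster = 4L, seed = seed + 7L)
write_bed(peaks, file.path(out, "atac_peaks.bed"))

## differential tables with truth labels
truth <- make_truth_genes(n_genes = cfg$n_genes, seed = seed + 11L)
write.table(truth, file.path(out, "gene_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tabs <- simulate_differential_tables(truth, seed = seed + 13L)
for (nm in names(tabs)) {
  write_diff_table(tabs[[nm]], file.path(out, paste0(nm, ".tsv")))
}
cat("synthetic study written to", out, "\n")
cat(sprintf("  compartment arm: %d bins @ %d bp, %d clusters, 2x2 replicates\n",
            cfg$comp_n_bins, cfg$comp_bin_size, nrow(ccl)))
cat(sprintf("  loop arm: %d bins @ %d bp, %d injected loops (%d intra / %d inter)\n",
            cfg$loop_n_bins, cfg$loop_bin_size, nrow(sim$truth$loops),
            sum(sim$truth$loops$class == "intra"),
            sum(sim$truth$loops$class == "inter")))
cat(sprintf("  %d genes, %d peaks\n", cfg$n_genes, nrow(peaks)))
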