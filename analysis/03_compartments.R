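#!/usr/bin/env Rscript
# Stage 3: A/B compartments. Merge replicates per condition, call the
# activity-phased compartment eigenvector, measure saddle
# compartmentalization strength, and quantify cluster-versus-control
# delta-PC1 with the unpaired rank-sum test.
suppressPackageStartupMessages(library(ifn3d))

dat <- "results/data"
out <- "results"
cfg <- default_config()
bs <- cfg$comp_bin_size

read2 <- function(stub) {
  merge_matrices(list(
    read_contact_matrix(file.path(dat, sprintf("comp_%s_rep1.tsv", stub))),
    read_contact_matrix(file.path(dat, sprintf("comp_%s_rep2.tsv", stub)))))
}
mu <- read2("untreated")
mt <- read2("treated")
n <- n_bins(mu)
activity <- read_bedgraph_track(file.path(dat, "activity_40kb.bedgraph"),
                                "chr1", bs, n)
clusters <- read_bed(file.path(dat, "clusters_40kb.bed"))
clusters$cluster_id <- clusters$name

prep <- function(m) ice_balance(mask_low_coverage(m, cfg$mask_quantile))
bu <- prep(mu); bt <- prep(mt)
cu <- compute_compartment_track(bu, activity)
ct <- compute_compartment_track(bt, activity)
cat(sprintf("phasing: eigenvector %d (untreated, r = %.3f), %d (treated, r = %.3f)\n",
            cu$eigen_rank, cu$phase_correlation,
            ct$eigen_rank, ct$phase_correlation))
write_bedgraph_track(cu$pc1, "chr1", bs, file.path(out, "pc1_untreated.bedgraph"))
write_bedgraph_track(ct$pc1, "chr1", bs, file.path(out, "pc1_treated.bedgraph"))
write_bedgraph_track(ct$pc1 - cu$pc1, "chr1", bs,
                     file.path(out, "delta_pc1.bedgraph"))

su <- saddle_strength(bu, cu$pc1, cfg$saddle_quantiles, cfg$corner_fraction)
st <- saddle_strength(bt, ct$pc1, cfg$saddle_quantiles, cfg$corner_fraction)
write.table(round(su$saddle, 4), file.path(out, "saddle_untreated.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(round(st$saddle, 4), file.path(out, "saddle_treated.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
cat(sprintf("saddle strength: untreated %.3f, treated %.3f\n",
            su$strength, st$strength))

dstat <- delta_pc1_regions(ct$pc1, cu$pc1, clusters, bin_size = bs,
                           chrom_length = n * bs,
                           control_offset = cfg$control_offset)
write.table(dstat, file.path(out, "delta_pc1_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
rs <- rank_sum_test(dstat$mean_delta,
                    c(dstat$control_up, dstat$control_down))
cat(sprintf("clusters with delta-PC1 above both controls: %d/%d\n",
            sum(dstat$mean_delta > dstat$control_up &
                  dstat$mean_delta > dstat$control_down), nrow(dstat)))
cat(sprintf("rank-sum cluster vs control means: W = %.0f, p = %.2g\n",
            rs$statistic, rs$p))
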