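#!/usr/bin/env Rscript
# Stage 4: chromatin loops. Detect dots on the fusion map (sum of both
# conditions), quantify their template-correlation scores per condition on
# coverage-equalized maps, classify them as intra-/inter-cluster and
# compare the median score ratios; score reproducibility as Spearman rho.
suppressPackageStartupMessages(library(ifn3d))

dat <- "results/data"
out <- "results"
cfg <- default_config()
bs <- cfg$loop_bin_size

mu <- read_contact_matrix(file.path(dat, "loop_untreated.tsv"))
mt <- read_contact_matrix(file.path(dat, "loop_treated.tsv"))
clusters <- read_bed(file.path(dat, "clusters_10kb.bed"))
clusters$cluster_id <- clusters$name
truth <- read.table(file.path(dat, "loop_truth.tsv"), header = TRUE,
                    sep = "\t")

kernel <- loop_kernel(cfg$kernel_size)
fusion <- merge_matrices(list(mu, mt))
fb <- ice_balance(mask_low_coverage(fusion, cfg$mask_quantile))
smap <- score_map(fb, kernel, min_d = cfg$loop_min_d, max_d = cfg$loop_max_d)
calls <- detect_loops(smap, cfg$loop_threshold, chrom = "chr1",
                      bin_size = bs)
write_bedpe(calls, file.path(out, "loops_fusion.bedpe"))
matched <- outer(calls$bin1, truth$a1, function(x, y) abs(x - y) <= 2) &
  outer(calls$bin2, truth$a2, function(x, y) abs(x - y) <= 2)
cat(sprintf("fusion map: %d calls above %.2f; %d/%d injected loops recovered\n",
            nrow(calls), cfg$loop_threshold, sum(colSums(matched) > 0),
            nrow(truth)))

qt <- quantify_loops(calls, list(untreated = mu, treated = mt),
                     kernel = kernel, seed = cfg$seed,
                     min_d = cfg$loop_min_d, max_d = cfg$loop_max_d,
                     mask_quantile = cfg$mask_quantile)
write.table(qt, file.path(out, "loop_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

qcalls <- cbind(calls[, c("chrom", "start1", "end1", "start2", "end2")],
                untreated = qt$untreated, treated = qt$treated)
for (cond in c("untreated", "treated")) {
  st <- classify_cluster_loops(qcalls, clusters,
                               max_length = cfg$loop_max_length,
                               score_col = cond)
  ratios <- vapply(st, function(x) x$ratio, numeric(1))
  cat(sprintf("%s inter/intra score ratios: %s\n", cond,
              paste(sprintf("%s = %.3f", clusters$cluster_id, ratios),
                    collapse = ", ")))
  write.table(
    data.frame(cluster_id = clusters$cluster_id, ratio = ratios,
               n_intra = vapply(st, function(x) length(x$intra), 1L),
               n_inter = vapply(st, function(x) length(x$inter), 1L)),
    file.path(out, sprintf("cluster_ratios_%s.tsv", cond)), sep = "\t",
    quote = FALSE, row.names = FALSE)
}

# reproducibility: quantify on two half-coverage pseudo-replicates
half <- round(min(total_counts(mu), total_counts(mt)) / 2)
sub_a <- subsample_counts(mu, half, seed = 21)
sub_b <- subsample_counts(mu, half, seed = 22)
qr <- quantify_loops(calls, list(a = sub_a, b = sub_b), kernel = kernel,
                     seed = 3, min_d = cfg$loop_min_d,
                     max_d = cfg$loop_max_d,
                     mask_quantile = cfg$mask_quantile)
keep <- abs(qcalls$start2 - qcalls$start1) < cfg$loop_max_length
rho <- loop_score_correlation(
  data.frame(loop_id = qr$loop_id[keep], score = qr$a[keep]),
  data.frame(loop_id = qr$loop_id[keep], score = qr$b[keep]))
cat(sprintf("pseudo-replicate loop-score Spearman rho (< %d kb): %.3f\n",
            cfg$loop_max_length / 1000, rho))
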