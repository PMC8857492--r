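#' Select regulatory (non-genic) accessible peaks within clusters
#'
#' Keeps peaks that intersect a cluster region and intersect no gene-body
#' interval (peaks over gene bodies tend to be broad and uninformative for
#' regulatory elements), and assigns each surviving peak its cluster id.
#'
#' @param peaks data frame `chrom, start, end, peak_id`.
#' @param clusters disjoint data frame `chrom, start, end` and optionally
#'   `cluster_id`.
#' @param gene_bodies data frame `chrom, start, end`, or NULL.
#' @return filtered peak data frame with a `cluster_id` column.
#' @export
select_regulatory_peaks <- function(peaks, clusters, gene_bodies = NULL) {
  ids <- if ("cluster_id" %in% names(clusters)) clusters$cluster_id else
    sprintf("cluster_%d", seq_len(nrow(clusters)))
  keep <- logical(nrow(peaks))
  cl_id <- character(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    p <- peaks[k, ]
    hits <- which(clusters$chrom == p$chrom &
                    intervals_overlap(p$start, p$end, clusters$start,
                                      clusters$end))
    if (length(hits) > 1) {
      stop("peak ", p$peak_id, " intersects multiple clusters; clusters must be disjoint")
    }
    if (length(hits) == 0) next
    if (!is.null(gene_bodies)) {
      g <- gene_bodies[gene_bodies$chrom == p$chrom, , drop = FALSE]
      if (nrow(g) > 0 && any(intervals_overlap(p$start, p$end, g$start,
                                               g$end))) next
    }
    keep[k] <- TRUE
    cl_id[k] <- ids[hits]
  }
  out <- peaks[keep, , drop = FALSE]
  out$cluster_id <- cl_id[keep]
  rownames(out) <- NULL
  out
}

#' Mean balanced contact between two intervals
#'
#' Mean of balanced (ICE-corrected) values over all bin pairs `(i, j)` with
#' bin `i` overlapping interval `a` and bin `j` overlapping interval `b`.
#'
#' @param a,b intervals as lists/rows with `start`, `end` (same chromosome
#'   as `m`).
#' @param m a balanced `contact_matrix`.
#' @param b_values optional precomputed [balanced_values()] matrix.
#' @return mean balanced value, or NA if every covered cell is masked.
#' @export
pair_interaction_strength <- function(a, b, m, b_values = NULL) {
  if (!is.null(a$chrom) && !is.null(b$chrom) && a$chrom != b$chrom) {
    stop("peaks on different chromosomes")
  }
  if (is.null(b_values)) b_values <- balanced_values(m)
  n <- n_bins(m)
  bi <- bins_overlapping(a$start, a$end, m$bin_size, n)
  bj <- bins_overlapping(b$start, b$end, m$bin_size, n)
  if (length(bi) == 0 || length(bj) == 0) return(NA_real_)
  v <- b_values[bi, bj, drop = FALSE]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Construct the two distance-matched control pairs for a peak pair
#'
#' For a real pair A-B (B downstream of A) with midpoint distance `d`:
#' control A' is an interval of B's size centered `d` upstream of A's
#' midpoint (paired with A); control B' is an interval of A's size centered
#' `d` downstream of B's midpoint (paired with B). Intervals are placed by
#' center with half-open rounding toward the start on odd sizes, so each
#' valid control preserves the real pair's midpoint distance exactly.
#' Controls extending outside `[0, chrom_length)` are flagged invalid.
#'
#' @param a,b rows/lists with `start`, `end`; `b` must start after `a`.
#' @param chrom_length chromosome length in bp.
#' @return list of two controls, each with `anchor` ("a" or "b"), `start`,
#'   `end`, `valid`.
#' @export
build_control_pairs <- function(a, b, chrom_length) {
  stopifnot(b$start > a$start)
  mid_a <- interval_midpoint(a$start, a$end)
  mid_b <- interval_midpoint(b$start, b$end)
  d <- mid_b - mid_a
  place <- function(center, size) {
    start <- center - floor(size / 2)
    list(start = start, end = start + size)
  }
  ctrl_a <- place(mid_a - d, b$end - b$start)
  ctrl_b <- place(mid_b + d, a$end - a$start)
  list(
    list(anchor = "a", start = ctrl_a$start, end = ctrl_a$end,
         valid = ctrl_a$start >= 0 && ctrl_a$end <= chrom_length),
    list(anchor = "b", start = ctrl_b$start, end = ctrl_b$end,
         valid = ctrl_b$start >= 0 && ctrl_b$end <= chrom_length)
  )
}

#' Interaction strengths for all within-cluster peak pairs plus controls
#'
#' Enumerates all peak pairs annotated to the same cluster, computes the real
#' interaction strength and the mean strength of the (valid) constructed
#' control pairs.
#'
#' @param peaks output of [select_regulatory_peaks()].
#' @param m a balanced `contact_matrix` for the peaks' chromosome.
#' @param chrom_length chromosome length in bp.
#' @return data frame with one row per pair: `cluster_id`, `peak_a`,
#'   `peak_b`, `real`, `control` (mean of valid controls, NA if none),
#'   `n_valid_controls`.
#' @export
cluster_pair_strengths <- function(peaks, m, chrom_length) {
  bv <- balanced_values(m)
  rows <- list()
  for (cl in unique(peaks$cluster_id)) {
    pk <- peaks[peaks$cluster_id == cl, , drop = FALSE]
    pk <- pk[order(pk$start), , drop = FALSE]
    if (nrow(pk) < 2) next
    for (i in seq_len(nrow(pk) - 1)) {
      for (j in (i + 1):nrow(pk)) {
        a <- pk[i, ]; b <- pk[j, ]
        real <- pair_interaction_strength(a, b, m, b_values = bv)
        ctrls <- build_control_pairs(a, b, chrom_length)
        cs <- vapply(ctrls, function(ct) {
          if (!ct$valid) return(NA_real_)
          anchor <- if (ct$anchor == "a") a else b
          pair_interaction_strength(anchor, ct, m, b_values = bv)
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          cluster_id = cl, peak_a = a$peak_id, peak_b = b$peak_id,
          real = real, control = if (all(is.na(cs))) NA_real_ else
            mean(cs, na.rm = TRUE),
          n_valid_controls = sum(!is.na(cs)))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cluster_id = character(0), peak_a = character(0),
                      peak_b = character(0), real = numeric(0),
                      control = numeric(0), n_valid_controls = integer(0)))
  }
  do.call(rbind, rows)
}

#' Paired enrichment test of real versus control interaction strengths
#'
#' Pairs lacking a real strength or any valid control are dropped (count
#' reported); the remaining real-minus-control differences are tested with
#' the two-sided Wilcoxon signed-rank test ([signed_rank_test()]).
#'
#' @param pairs a [cluster_pair_strengths()] table.
#' @return list with `n`, `n_dropped`, `statistic`, `p`, `median_real`,
#'   `median_control`, `degenerate`.
#' @export
paired_enrichment_test <- function(pairs) {
  ok <- !is.na(pairs$real) & !is.na(pairs$control)
  n_dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no pair with a real strength and a valid control")
  res <- signed_rank_test(pairs$real, pairs$control)
  list(n = nrow(pairs), n_dropped = n_dropped,
       statistic = res$statistic, p = res$p,
       median_real = stats::median(pairs$real),
       median_control = stats::median(pairs$control),
       degenerate = res$degenerate)
}
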