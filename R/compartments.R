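#' A/B compartment eigenvector phased by an activity track
#'
#' Extracts the first three eigenvectors (by eigenvalue magnitude) of the
#' mean-centered observed-over-expected matrix `O/E - 1` over unmasked bins,
#' selects the one with the largest absolute Pearson correlation to the
#' activity track (e.g. RNA-seq coverage), and flips its sign so that the
#' correlation is positive (positive PC1 = A compartment). The selected
#' eigenvector is scaled by the square root of its eigenvalue magnitude, so
#' the PC1 amplitude tracks compartmentalization strength and differences
#' between conditions are meaningful. `method = "correlation"` instead
#' eigendecomposes the Pearson correlation matrix of the O/E rows (the
#' classic compartment-calling variant; its row-wise normalization discards
#' amplitude, so it is less sensitive for between-condition comparisons).
#'
#' @param m a masked, balanced `contact_matrix`.
#' @param activity numeric per-bin activity values aligned to the binning.
#' @param method `"oe"` (default) or `"correlation"`, see above.
#' @param oe optional precomputed [observed_over_expected()] matrix.
#' @param weak_threshold absolute phasing correlation below which the result
#'   is flagged degenerate (no compartment signal).
#' @return list with `pc1` (per-bin values, NA on masked bins), `eigen_rank`,
#'   `phase_correlation` and `degenerate`.
#' @export
compute_compartment_track <- function(m, activity, method = c("oe",
                                                              "correlation"),
                                      oe = NULL, weak_threshold = 0.3) {
  method <- match.arg(method)
  n <- n_bins(m)
  stopifnot(length(activity) == n)
  if (is.null(oe)) oe <- observed_over_expected(m)
  keep <- !m$mask
  sub <- oe[keep, keep, drop = FALSE]
  if (method == "correlation") {
    sub[!is.finite(sub)] <- NA
    vars <- apply(sub, 1, stats::var, na.rm = TRUE)
    if (any(is.na(vars) | vars == 0)) {
      stop("degenerate matrix: zero-variance O/E row(s) among unmasked bins")
    }
    A <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    if (any(!is.finite(A))) stop("degenerate correlation matrix")
  } else {
    A <- sub - 1
    A[!is.finite(A)] <- 0  # distances without data carry no signal
    if (all(A == 0)) stop("degenerate matrix: O/E carries no signal")
  }
  eg <- eigen(A, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[1:3]
  act <- activity[keep]
  if (stats::sd(act) == 0) stop("activity track constant: phasing impossible")
  rs <- vapply(ord, function(k) {
    v <- eg$vectors[, k]
    if (stats::sd(v) == 0) return(0)
    stats::cor(v, act)
  }, numeric(1))
  pick <- which.max(abs(rs))
  v <- eg$vectors[, ord[pick]]
  if (method == "oe") v <- v * sqrt(abs(eg$values[ord[pick]]))
  r <- rs[pick]
  if (r < 0) {
    v <- -v
    r <- -r
  }
  pc1 <- rep(NA_real_, n)
  pc1[keep] <- v
  list(pc1 = pc1, eigen_rank = pick, phase_correlation = r,
       degenerate = r < weak_threshold)
}

#' Saddle plot and compartmentalization strength
#'
#' Unmasked bins are ranked by their compartment score into `n_quantiles`
#' equal-occupancy groups; `saddle[a, b]` is the mean O/E over cell pairs
#' with one bin in group `a` and the other in group `b` (same-bin cells
#' excluded). The strength is `(mean AA corner + mean BB corner) /
#' (2 * mean AB corner)` over the `corner_fraction` outermost groups.
#'
#' @param m a balanced `contact_matrix`, or NULL if `oe` is given.
#' @param pc1 per-bin compartment score (NA allowed on masked bins).
#' @param n_quantiles number of rank groups `q`.
#' @param corner_fraction fraction of groups per corner (0, 0.5].
#' @param oe optional O/E matrix (bins with NA `pc1` ignored).
#' @return list with `saddle` (q x q, ordered from most-B to most-A group)
#'   and `strength`.
#' @export
saddle_strength <- function(m = NULL, pc1, n_quantiles = 10L,
                            corner_fraction = 0.2, oe = NULL) {
  stopifnot(corner_fraction > 0, corner_fraction <= 0.5)
  if (is.null(oe)) oe <- observed_over_expected(m)
  n <- nrow(oe)
  stopifnot(length(pc1) == n)
  keep <- which(!is.na(pc1))
  q <- as.integer(n_quantiles)
  if (q > length(keep)) stop("more quantile groups than scored bins")
  ord <- keep[order(pc1[keep])]
  grp <- integer(n)
  grp[ord] <- as.integer(cut(seq_along(ord), breaks = q, labels = FALSE))
  saddle <- matrix(NA_real_, q, q)
  for (a in seq_len(q)) {
    ia <- which(grp == a)
    for (b in a:q) {
      ib <- which(grp == b)
      v <- oe[ia, ib, drop = FALSE]
      if (a == b) v[cbind(seq_along(ia), seq_along(ia))] <- NA
      v <- v[!is.na(v)]
      saddle[a, b] <- saddle[b, a] <- if (length(v)) mean(v) else NA_real_
    }
  }
  nc <- max(1L, round(corner_fraction * q))
  bb <- saddle[seq_len(nc), seq_len(nc)]
  aa <- saddle[q - seq_len(nc) + 1L, q - seq_len(nc) + 1L]
  ab <- saddle[seq_len(nc), q - seq_len(nc) + 1L]
  strength <- (mean(aa, na.rm = TRUE) + mean(bb, na.rm = TRUE)) /
    (2 * mean(ab, na.rm = TRUE))
  list(saddle = saddle, strength = strength)
}

#' Region-versus-control differences of compartment scores
#'
#' For each region, the mean of `pc1_treated - pc1_untreated` over bins whose
#' interval intersects the region, together with the same statistic on two
#' size-matched control intervals offset by `control_offset` bp up- and
#' downstream (offset measured start-to-start). Controls extending beyond the
#' chromosome are flagged invalid (NA) rather than truncated.
#'
#' @param pc1_treated,pc1_untreated per-bin compartment scores on a shared
#'   binning.
#' @param regions data frame with `start`, `end` (0-based half-open bp) and
#'   optionally `region_id`.
#' @param bin_size bin width in bp (default 40 kb).
#' @param chrom_length chromosome length in bp (defaults to the track end).
#' @param control_offset control displacement in bp (default 1 Mb).
#' @return data frame with per-region mean delta and the two control means.
#' @export
delta_pc1_regions <- function(pc1_treated, pc1_untreated, regions,
                              bin_size = 40000L, chrom_length = NULL,
                              control_offset = 1e6) {
  stopifnot(length(pc1_treated) == length(pc1_untreated))
  n <- length(pc1_treated)
  if (is.null(chrom_length)) chrom_length <- n * bin_size
  delta <- pc1_treated - pc1_untreated
  region_mean <- function(start, end) {
    if (start < 0 || end > chrom_length) return(NA_real_)
    idx <- bins_overlapping(start, end, bin_size, n)
    v <- delta[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }
  ids <- if ("region_id" %in% names(regions)) regions$region_id else
    sprintf("region_%d", seq_len(nrow(regions)))
  out <- data.frame(region_id = ids, start = regions$start, end = regions$end,
                    mean_delta = NA_real_, control_up = NA_real_,
                    control_down = NA_real_)
  for (k in seq_len(nrow(regions))) {
    st <- regions$start[k]; en <- regions$end[k]; len <- en - st
    out$mean_delta[k] <- region_mean(st, en)
    out$control_up[k] <- region_mean(st - control_offset,
                                     st - control_offset + len)
    out$control_down[k] <- region_mean(st + control_offset,
                                       st + control_offset + len)
  }
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test for two unpaired groups
#'
#' Exact two-sided p-value for combined sample size <= 20 (without ties),
#' normal approximation with tie correction otherwise. If all values across
#' both groups are identical the result is flagged degenerate with p = 1.
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `statistic`, `p`, `degenerate`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (length(unique(c(group_a, group_b))) == 1) {
    return(list(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  exact <- (length(group_a) + length(group_b)) <= 20
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p = res$p.value, degenerate = FALSE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Exact for n <= 25 (without ties/zeros), normal approximation with
#' zero-difference exclusion otherwise.
#'
#' @param x,y paired numeric vectors (`x - y` is tested against zero).
#' @return list with `statistic`, `p`, `degenerate`.
#' @export
signed_rank_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  exact <- length(d) <= 25
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p = res$p.value, degenerate = FALSE)
}
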