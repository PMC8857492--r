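#' Dot-shaped loop scoring template
#'
#' A centered Gaussian dot minus its mean, standardized to unit variance: the
#' template slid over contact maps for loop scoring. Zero mean and unit
#' variance make the Pearson correlation with a map window well-conditioned;
#' the centre is enriched relative to the border by construction.
#'
#' @param size odd kernel side length in bins (17 suits 10 kb maps, 9 suits
#'   5 kb maps).
#' @param sigma Gaussian sd in bins.
#' @return `size x size` numeric matrix.
#' @export
loop_kernel <- function(size = 17L, sigma = 1.5) {
  stopifnot(size %% 2 == 1, size >= 3, sigma > 0)
  h <- (size - 1L) / 2L
  x <- seq(-h, h)
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g <- g - mean(g)
  g / stats::sd(as.vector(g))
}

#' Template-correlation score map
#'
#' Slides the kernel over `log(1 + O/E)` of a balanced contact map and, for
#' every upper-triangle cell within the scanning band, computes the Pearson
#' correlation between the kernel and the local window over valid (in-bounds,
#' unmasked) cells. Windows with less than `min_valid_fraction` valid cells
#' or zero variance score NA.
#'
#' @param m a masked, balanced `contact_matrix`.
#' @param kernel a [loop_kernel()].
#' @param min_d,max_d scanning band limits in bp (anchor separation).
#' @param min_valid_fraction minimum fraction of valid window cells.
#' @param oe optional precomputed O/E matrix.
#' @return n x n matrix of scores (upper triangle; NA elsewhere).
#' @export
score_map <- function(m, kernel, min_d = 0, max_d = 1e7,
                      min_valid_fraction = 0.8, oe = NULL) {
  n <- n_bins(m)
  k <- nrow(kernel)
  h <- (k - 1L) / 2L
  dmin <- max(1L, as.integer(ceiling(min_d / m$bin_size)))
  dmax <- min(n - 1L, as.integer(floor(max_d / m$bin_size)))
  if (dmin > dmax) stop("kernel/scanning band excludes every cell")
  if (is.null(oe)) oe <- observed_over_expected(m)
  L <- log1p(oe)
  kv <- as.vector(kernel)
  k2 <- k * k
  scores <- matrix(NA_real_, n, n)
  for (d in dmin:dmax) {
    for (i in seq_len(n - d)) {
      j <- i + d
      ri <- (i - h):(i + h)
      rj <- (j - h):(j + h)
      ok_i <- ri >= 1L & ri <= n
      ok_j <- rj >= 1L & rj <= n
      win <- matrix(NA_real_, k, k)
      win[ok_i, ok_j] <- L[ri[ok_i], rj[ok_j]]
      valid <- !is.na(win)
      if (sum(valid) < min_valid_fraction * k2) next
      wv <- win[valid]
      if (stats::sd(wv) == 0) next
      scores[i, j] <- stats::cor(kv[valid], wv)
    }
  }
  scores
}

#' Detect loops as local maxima of a score map
#'
#' Cells scoring above `threshold` that are local maxima over their eight
#' neighbours are kept greedily best-first, discarding any candidate within
#' `min_separation` bins (Chebyshev distance) of an already accepted call.
#'
#' @param scores a [score_map()] result.
#' @param threshold minimum Pearson score (exclusive).
#' @param min_separation minimum Chebyshev distance between calls, in bins.
#' @param chrom,bin_size annotation copied onto the calls.
#' @return data frame `chrom, bin1, bin2, start1, end1, start2, end2, score`
#'   (0-based bins and bp intervals).
#' @export
detect_loops <- function(scores, threshold = 0.35, min_separation = 3L,
                         chrom = "chr1", bin_size = 10000L) {
  stopifnot(threshold > -1, threshold < 1)
  n <- nrow(scores)
  cand <- which(!is.na(scores) & scores > threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    s <- scores[i, j]
    ni <- max(1, i - 1):min(n, i + 1)
    nj <- max(1, j - 1):min(n, j + 1)
    nb <- scores[ni, nj, drop = FALSE]
    nb[is.na(nb)] <- -Inf
    keep[k] <- s >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(empty_loop_calls(chrom))
  }
  ord <- order(scores[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), 0, 2)
  sel <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (nrow(acc) == 0 ||
        all(pmax(abs(acc[, 1] - cand[k, 1]),
                 abs(acc[, 2] - cand[k, 2])) >= min_separation)) {
      acc <- rbind(acc, cand[k, ])
      sel[k] <- TRUE
    }
  }
  cand <- cand[sel, , drop = FALSE]
  b1 <- cand[, 1] - 1L; b2 <- cand[, 2] - 1L
  out <- data.frame(chrom = chrom, bin1 = b1, bin2 = b2,
                    start1 = b1 * bin_size, end1 = (b1 + 1) * bin_size,
                    start2 = b2 * bin_size, end2 = (b2 + 1) * bin_size,
                    score = scores[cand])
  out[order(out$bin1, out$bin2), , drop = FALSE]
}

empty_loop_calls <- function(chrom = character(0)) {
  data.frame(chrom = character(0), bin1 = integer(0), bin2 = integer(0),
             start1 = numeric(0), end1 = numeric(0), start2 = numeric(0),
             end2 = numeric(0), score = numeric(0))
}

#' Quantify loop scores per condition at fixed positions
#'
#' Implements the coverage-equalized quantification step: each condition's
#' map is subsampled to the smallest contact total, re-masked and balanced,
#' and the template correlation is evaluated only at the given anchor
#' positions (typically detected on the fusion map, see [merge_matrices()]).
#'
#' @param positions loop-call data frame with `bin1`, `bin2` (0-based).
#' @param matrices named list of `contact_matrix` objects, one per condition.
#' @param kernel a [loop_kernel()].
#' @param seed RNG seed for the subsampling.
#' @param min_d,max_d scanning band in bp; positions outside score NA.
#' @param mask_quantile low-coverage mask quantile applied after subsampling.
#' @return data frame with `loop_id`, `bin1`, `bin2` and one score column per
#'   condition.
#' @export
quantify_loops <- function(positions, matrices, kernel = loop_kernel(),
                           seed = 1L, min_d = 0, max_d = 1e7,
                           mask_quantile = 0) {
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)))
  target <- min(vapply(matrices, total_counts, numeric(1)))
  out <- data.frame(loop_id = sprintf("loop_%d", seq_len(nrow(positions))),
                    bin1 = positions$bin1, bin2 = positions$bin2)
  for (ci in seq_along(matrices)) {
    m <- subsample_counts(matrices[[ci]], target, seed = seed + ci)
    m <- mask_low_coverage(m, mask_quantile)
    m <- ice_balance(m)
    sc <- score_map(m, kernel, min_d = min_d, max_d = max_d)
    idx <- cbind(positions$bin1 + 1L, positions$bin2 + 1L)
    out[[names(matrices)[ci]]] <- sc[idx]
  }
  out
}

#' Classify loops as intra- or inter-cluster and compute ratio statistics
#'
#' A loop is attributed to a cluster when at least one anchor midpoint lies
#' inside it; loops longer than `max_length` (anchor midpoint separation) or
#' scoring below `min_score` are excluded. Intra-cluster: both anchors in the
#' same cluster; inter-cluster: exactly one anchor inside. The summary ratio
#' per cluster is `median(inter) / median(intra)`.
#'
#' @param loops loop-call data frame with `chrom`, `start1`, `end1`,
#'   `start2`, `end2`, `score`.
#' @param clusters non-overlapping data frame `chrom`, `start`, `end` and
#'   optionally `cluster_id`.
#' @param max_length maximum loop length in bp (default 500 kb).
#' @param min_score optional score filter (NULL = keep all).
#' @param score_col column of `loops` holding the score to summarize.
#' @return list of per-cluster stats: `cluster_id`, `intra`, `inter`, `ratio`.
#' @export
classify_cluster_loops <- function(loops, clusters, max_length = 5e5,
                                   min_score = NULL, score_col = "score") {
  ids <- if ("cluster_id" %in% names(clusters)) clusters$cluster_id else
    sprintf("cluster_%d", seq_len(nrow(clusters)))
  for (ch in unique(clusters$chrom)) {
    cl <- clusters[clusters$chrom == ch, , drop = FALSE]
    if (nrow(cl) > 1) {
      cl <- cl[order(cl$start), , drop = FALSE]
      if (any(cl$end[-nrow(cl)] > cl$start[-1])) {
        stop("overlapping clusters on ", ch)
      }
    }
  }
  mid1 <- interval_midpoint(loops$start1, loops$end1)
  mid2 <- interval_midpoint(loops$start2, loops$end2)
  len <- abs(mid2 - mid1)
  sc <- loops[[score_col]]
  keep <- len <= max_length & !is.na(sc)
  if (!is.null(min_score)) keep <- keep & sc >= min_score
  assign_cluster <- function(chrom, pos) {
    hit <- which(clusters$chrom == chrom & clusters$start <= pos &
                   pos < clusters$end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  out <- lapply(seq_len(nrow(clusters)), function(k) {
    list(cluster_id = ids[k], intra = numeric(0), inter = numeric(0),
         ratio = NA_real_)
  })
  for (r in which(keep)) {
    c1 <- assign_cluster(loops$chrom[r], mid1[r])
    c2 <- assign_cluster(loops$chrom[r], mid2[r])
    if (is.na(c1) && is.na(c2)) next
    if (!is.na(c1) && !is.na(c2) && c1 == c2) {
      out[[c1]]$intra <- c(out[[c1]]$intra, sc[r])
    } else {
      for (cc in unique(stats::na.omit(c(c1, c2)))) {
        out[[cc]]$inter <- c(out[[cc]]$inter, sc[r])
      }
    }
  }
  for (k in seq_along(out)) {
    if (length(out[[k]]$intra) > 0 && length(out[[k]]$inter) > 0 &&
        stats::median(out[[k]]$intra) != 0) {
      out[[k]]$ratio <- stats::median(out[[k]]$inter) /
        stats::median(out[[k]]$intra)
    }
  }
  out
}

#' Spearman correlation of loop scores between two samples
#'
#' Reproducibility of quantified loop scores: rank correlation over loops
#' present with defined scores in both tables.
#'
#' @param scores_a,scores_b data frames with `loop_id` and `score`.
#' @return Spearman rho.
#' @export
loop_score_correlation <- function(scores_a, scores_b) {
  m <- merge(scores_a[, c("loop_id", "score")],
             scores_b[, c("loop_id", "score")], by = "loop_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 shared loops with defined scores")
  stats::cor(m$score.x, m$score.y, method = "spearman")
}
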