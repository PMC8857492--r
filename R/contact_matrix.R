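#' Binned cis contact matrix for one chromosome
#'
#' Container for a symmetric binned Hi-C contact map: raw counts, bin size,
#' optional ICE balancing weights and a per-bin exclusion mask. Bin `i`
#' (0-based) covers the half-open interval `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param counts symmetric, non-negative numeric matrix of raw counts.
#' @param chrom chromosome name.
#' @param bin_size bin width in base pairs.
#' @param weights optional per-bin balancing factors (NA on masked bins).
#' @param mask logical vector, `TRUE` marks excluded low-coverage bins.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", bin_size = 10000L,
                           weights = NULL, mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be a square matrix")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("counts must be symmetric")
  }
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  if (!is.null(weights)) stopifnot(length(weights) == n)
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         counts = unname(counts), weights = weights, mask = mask),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %d bp, %.0f contacts, %d masked, %s\n",
              x$chrom, n_bins(x), x$bin_size, total_counts(x), sum(x$mask),
              if (is.null(x$weights)) "unbalanced" else "balanced"))
  invisible(x)
}

#' Number of bins
#' @param m a `contact_matrix`.
#' @export
n_bins <- function(m) nrow(m$counts)

#' Total contact count (upper triangle including the diagonal)
#'
#' The matrix stores each cis contact twice (symmetry); the contact total
#' counts every pair once.
#' @param m a `contact_matrix`.
#' @export
total_counts <- function(m) {
  sum(m$counts[upper.tri(m$counts, diag = TRUE)])
}

#' Balanced (ICE-corrected) matrix values
#'
#' Returns `counts[i, j] * w[i] * w[j]`; rows/columns of masked bins are NA.
#' @param m a balanced `contact_matrix`.
#' @export
balanced_values <- function(m) {
  if (is.null(m$weights)) stop("matrix is not balanced; run ice_balance() first")
  w <- m$weights
  b <- m$counts * outer(w, w)
  b[m$mask, ] <- NA_real_
  b[, m$mask] <- NA_real_
  b
}

#' Mask low-coverage bins
#'
#' Masks bins whose marginal count is zero or strictly below the `q`-quantile
#' of the nonzero marginals.
#'
#' @param m a `contact_matrix`.
#' @param q quantile in `[0, 1)`.
#' @export
mask_low_coverage <- function(m, q = 0.05) {
  stopifnot(q >= 0, q < 1)
  marg <- rowSums(m$counts)
  nz <- marg[marg > 0]
  mask <- marg == 0
  if (length(nz) > 0 && q > 0) {
    mask <- mask | marg < stats::quantile(nz, q, names = FALSE)
  }
  if (all(mask)) stop("all bins would be masked")
  m$mask <- mask
  m$weights <- NULL
  m
}

#' ICE balancing by iterative row-sum correction
#'
#' Iteratively divides per-bin weights by the current normalized row sums
#' until the coefficient of variation (CV) of unmasked row sums falls below
#' `tol`. Weights are then rescaled so the mean unmasked balanced row sum
#' equals 1. Masked bins get NA weights.
#'
#' @param m a masked `contact_matrix`.
#' @param tol convergence tolerance on the row-sum CV.
#' @param max_iter iteration cap.
#' @export
ice_balance <- function(m, tol = 1e-6, max_iter = 500L) {
  stopifnot(tol > 0)
  keep <- !m$mask
  if (!any(keep)) stop("all bins masked")
  cm <- m$counts[keep, keep, drop = FALSE]
  if (any(rowSums(cm) == 0)) {
    stop("unmasked bin with zero marginal; mask low-coverage bins first")
  }
  w <- rep(1, nrow(cm))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    b <- cm * outer(w, w)
    s <- rowSums(b)
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0  # single unmasked bin
    if (cv < tol) break
    w <- w / s
    w <- w / mean(w)
  }
  if (cv >= tol) {
    stop(sprintf("ICE did not converge in %d iterations (final CV %.3g)",
                 max_iter, cv))
  }
  # scale so mean unmasked balanced row sum is 1
  s <- rowSums(cm * outer(w, w))
  w <- w / sqrt(mean(s))
  weights <- rep(NA_real_, n_bins(m))
  weights[keep] <- w
  m$weights <- weights
  m
}

#' Distance-decay expected profile
#'
#' Mean contact value over unmasked cells at each bin distance `d`.
#'
#' @param m a `contact_matrix`.
#' @param use_balanced use balanced values (default) or raw counts.
#' @return numeric vector `E` with `E[d + 1]` the expectation at distance `d`;
#'   NA where no unmasked cells exist.
#' @export
expected_profile <- function(m, use_balanced = TRUE) {
  x <- if (use_balanced) balanced_values(m) else {
    cc <- m$counts
    cc[m$mask, ] <- NA_real_
    cc[, m$mask] <- NA_real_
    cc
  }
  n <- n_bins(m)
  E <- rep(NA_real_, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    v <- x[cbind(i, i + d)]
    v <- v[!is.na(v)]
    if (length(v) > 0) E[d + 1L] <- mean(v)
  }
  E
}

#' Observed-over-expected matrix
#'
#' Each cell divided by the expected value at its bin distance. Masked
#' rows/columns are NA. Every unmasked diagonal of the result has mean 1.
#'
#' @param m a balanced `contact_matrix` (or raw if `use_balanced = FALSE`).
#' @param E optional precomputed [expected_profile()].
#' @param use_balanced passed to [expected_profile()].
#' @export
observed_over_expected <- function(m, E = NULL, use_balanced = TRUE) {
  x <- if (use_balanced) balanced_values(m) else {
    cc <- m$counts
    cc[m$mask, ] <- NA_real_
    cc[, m$mask] <- NA_real_
    cc
  }
  if (is.null(E)) E <- expected_profile(m, use_balanced = use_balanced)
  n <- n_bins(m)
  d <- abs(row(x) - col(x))
  Ed <- matrix(E[d + 1L], n, n)
  bad <- !is.na(x) & x > 0 & (!is.na(Ed) & Ed == 0)
  if (any(bad)) stop("E(d) = 0 with observed > 0: inconsistent expected profile")
  oe <- x / Ed
  oe[Ed == 0] <- NA_real_
  oe
}

#' Merge replicate contact matrices
#'
#' Cell-wise sum of raw counts; the mask is recomputed on the merged counts
#' (zero-marginal bins masked), weights dropped.
#'
#' @param ms list of `contact_matrix` objects on the same chromosome/binning.
#' @export
merge_matrices <- function(ms) {
  stopifnot(length(ms) >= 1)
  ref <- ms[[1]]
  counts <- ref$counts
  for (m in ms[-1]) {
    if (!identical(dim(m$counts), dim(ref$counts)) ||
        m$chrom != ref$chrom || m$bin_size != ref$bin_size) {
      stop("matrices differ in chromosome, bin size or shape")
    }
    counts <- counts + m$counts
  }
  out <- contact_matrix(counts, ref$chrom, ref$bin_size)
  out$mask <- rowSums(counts) == 0
  out
}

#' Subsample a contact matrix to an exact total
#'
#' Multinomial thinning of upper-triangle counts to `target_total` contacts,
#' preserving symmetry. Marginal per-cell distribution is binomial with
#' probability `target_total / total`.
#'
#' @param m a `contact_matrix`.
#' @param target_total desired contact total (see [total_counts()]).
#' @param seed RNG seed.
#' @export
subsample_counts <- function(m, target_total, seed = NULL) {
  tot <- total_counts(m)
  if (target_total > tot) stop("target_total exceeds available contacts")
  if (target_total == tot) return(m)
  n <- n_bins(m)
  ut <- upper.tri(m$counts, diag = TRUE)
  v <- m$counts[ut]
  new_v <- with_seed(seed, {
    as.numeric(stats::rmultinom(1, size = target_total, prob = v))
  })
  counts <- matrix(0, n, n)
  counts[ut] <- new_v
  counts <- counts + t(counts) - diag(diag(counts), n)
  out <- contact_matrix(counts, m$chrom, m$bin_size, mask = m$mask)
  out
}

#' Log2 ratio map between two conditions
#'
#' `log2((m1 * s + p) / (m2 + p))` where `s` scales `m1`'s contact total to
#' `m2`'s; a fixed-bin comparison map highlighting gained/lost contacts.
#'
#' @param m1,m2 `contact_matrix` objects of identical shape.
#' @param pseudocount positive stabilizer `p`.
#' @export
log_ratio_map <- function(m1, m2, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (!identical(dim(m1$counts), dim(m2$counts))) stop("shape mismatch")
  s <- total_counts(m2) / total_counts(m1)
  log2((m1$counts * s + pseudocount) / (m2$counts + pseudocount))
}

#' Read / write the sparse TSV contact-matrix dialect
#'
#' Format: a header line `#chrom<TAB>bin_size<TAB>n_bins`, then one record
#' `bin_i<TAB>bin_j<TAB>count` per nonzero upper-triangle cell (0-based bins,
#' `i <= j`).
#'
#' @param path file path.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    stop("missing header line '#chrom\\tbin_size\\tn_bins'")
  }
  hd <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(hd) != 3) stop("malformed header")
  chrom <- hd[1]; bin_size <- as.integer(hd[2]); n <- as.integer(hd[3])
  counts <- matrix(0, n, n)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    rec <- utils::read.table(text = body, sep = "\t",
                             col.names = c("i", "j", "count"))
    for (k in seq_len(nrow(rec))) {
      i <- rec$i[k]; j <- rec$j[k]; cnt <- rec$count[k]
      line_no <- k + 1L
      if (is.na(i) || is.na(j) || i < 0 || j < 0 || i >= n || j >= n) {
        stop(sprintf("line %d: bin index outside [0, %d)", line_no, n))
      }
      if (i > j) stop(sprintf("line %d: lower-triangle record (i > j)", line_no))
      if (cnt < 0) stop(sprintf("line %d: negative count", line_no))
      counts[i + 1L, j + 1L] <- cnt
    }
    counts <- counts + t(counts) - diag(diag(counts), n)
  }
  contact_matrix(counts, chrom, bin_size)
}

#' @rdname read_contact_matrix
#' @param m a `contact_matrix` to write.
#' @export
write_contact_matrix <- function(m, path) {
  n <- n_bins(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%d\t%d", m$chrom, m$bin_size, n), con)
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                       format(m$counts[idx], trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}
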