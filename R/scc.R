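#' Stratum-adjusted correlation coefficient (SCC)
#'
#' Replicate similarity for Hi-C maps: both matrices are smoothed with a
#' `(2h+1) x (2h+1)` mean filter (edge-truncated, masked cells excluded),
#' then for each genomic-distance stratum `d = 1 .. max_distance / bin_size`
#' the Pearson correlation `r_d` of paired unmasked entries is combined with
#' weight `w_d = N_d * sd1_d * sd2_d` into `scc = sum(w r) / sum(w)`.
#' Strata with zero variance in either matrix contribute weight 0.
#'
#' @param m1,m2 `contact_matrix` objects with identical shape and binning.
#' @param h smoothing half-width in bins (`h = 0` disables smoothing).
#' @param max_distance maximum genomic distance in bp (default 1 Mb).
#' @return list with `scc`, per-stratum `r`, `w` and `n`.
#' @export
scc <- function(m1, m2, h = 1L, max_distance = 1e6) {
  if (!identical(dim(m1$counts), dim(m2$counts)) ||
      m1$bin_size != m2$bin_size) {
    stop("matrices differ in shape or bin size")
  }
  stopifnot(h >= 0)
  n <- n_bins(m1)
  mask <- m1$mask | m2$mask
  x1 <- m1$counts; x1[mask, ] <- NA; x1[, mask] <- NA
  x2 <- m2$counts; x2[mask, ] <- NA; x2[, mask] <- NA
  if (h > 0) {
    x1 <- box_smooth(x1, h)
    x2 <- box_smooth(x2, h)
  }
  kmax <- min(n - 1L, floor(max_distance / m1$bin_size))
  if (kmax < 1L) stop("max_distance smaller than one bin")
  r <- w <- nk <- rep(NA_real_, kmax)
  for (d in seq_len(kmax)) {
    i <- seq_len(n - d)
    a <- x1[cbind(i, i + d)]
    b <- x2[cbind(i, i + d)]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2) next
    s1 <- stats::sd(a); s2 <- stats::sd(b)
    nk[d] <- length(a)
    if (s1 == 0 || s2 == 0) {
      r[d] <- NA_real_; w[d] <- 0
    } else {
      r[d] <- stats::cor(a, b)
      w[d] <- length(a) * s1 * s2
    }
  }
  use <- !is.na(w) & w > 0
  if (!any(use)) stop("no distance stratum with variance in both matrices")
  list(scc = sum(w[use] * r[use]) / sum(w[use]),
       r = r, w = w, n = nk)
}

# Edge-truncated (2h+1)^2 moving-average filter that ignores NA cells:
# each cell becomes the mean of valid neighbours inside the window.
box_smooth <- function(x, h) {
  valid <- !is.na(x)
  x0 <- x
  x0[!valid] <- 0
  s <- box_sum(x0, h)
  cnt <- box_sum(valid + 0, h)
  out <- s / cnt
  out[cnt == 0] <- NA_real_
  out[!valid] <- NA_real_
  out
}

# sum over the (2h+1)^2 window, truncated at matrix edges (via 2D cumsum)
box_sum <- function(x, h) {
  n <- nrow(x); m <- ncol(x)
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # cs[j, i] = sum x[1:i, 1:j]
  cs <- t(cs)
  P <- matrix(0, n + 1L, m + 1L)
  P[-1, -1] <- cs
  i1 <- pmax(row(x) - h, 1L); i2 <- pmin(row(x) + h, n)
  j1 <- pmax(col(x) - h, 1L); j2 <- pmin(col(x) + h, m)
  out <- P[cbind(as.vector(i2) + 1L, as.vector(j2) + 1L)] -
    P[cbind(as.vector(i1), as.vector(j2) + 1L)] -
    P[cbind(as.vector(i2) + 1L, as.vector(j1))] +
    P[cbind(as.vector(i1), as.vector(j1))]
  matrix(out, n, m)
}
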