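#' Genome specification for synthetic data
#'
#' @param chroms chromosome names.
#' @param lengths chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @export
genome_spec <- function(chroms, lengths, bin_size) {
  stopifnot(length(chroms) == length(lengths), length(chroms) >= 1,
            all(lengths > 0), bin_size > 0)
  structure(list(chroms = as.character(chroms), lengths = as.numeric(lengths),
                 bin_size = as.integer(bin_size),
                 n_bins = as.integer(ceiling(lengths / bin_size))),
            class = "genome_spec")
}

#' Two-state compartment profile
#'
#' Alternating A/B blocks (`+1` / `-1`) of `block_width` bins, starting with A.
#'
#' @param n_bins number of bins.
#' @param block_width block width in bins.
#' @export
make_compartment_profile <- function(n_bins, block_width = 20L) {
  s <- rep(rep(c(1, -1), length.out = ceiling(n_bins / block_width)),
           each = block_width)
  s[seq_len(n_bins)]
}

#' Generative parameters for a synthetic Hi-C map
#'
#' The per-cell Poisson mean for bins `i <= j` is
#' `mu_ij = k * (1 + |i - j|)^(-alpha) * (1 + c_ij * s_i * s_j) *
#'  prod_loops(1 + L * exp(-((i - a1)^2 + (j - a2)^2) / (2 w^2)))`
#' with `k` set so the upper-triangle total equals `depth`.
#'
#' @param decay_exponent power-law distance-decay exponent `alpha > 0`.
#' @param depth expected contact total per chromosome.
#' @param compartment_profile per-bin score `s_i` in `[-1, 1]` (recycled per
#'   chromosome via [make_compartment_profile()] when NULL).
#' @param compartment_contrast checkerboard contrast `c >= 0`.
#' @param block_width compartment block width (bins) when the profile is built
#'   internally.
#' @param loops data frame with columns `chrom`, `a1`, `a2` (0-based anchor
#'   bins, `a1 < a2`), `L` (enrichment), `w` (width in bins); NULL for none.
#' @param seed integer RNG seed.
#' @export
synthetic_hic_params <- function(decay_exponent = 1, depth = 5e5,
                                 compartment_profile = NULL,
                                 compartment_contrast = 0.4,
                                 block_width = 20L,
                                 loops = NULL, seed = 1L) {
  stopifnot(decay_exponent > 0, depth > 0, compartment_contrast >= 0)
  if (!is.null(loops)) {
    stopifnot(all(c("chrom", "a1", "a2", "L", "w") %in% names(loops)),
              all(loops$L >= 0), all(loops$w > 0), all(loops$a1 < loops$a2))
  }
  structure(list(decay_exponent = decay_exponent, depth = depth,
                 compartment_profile = compartment_profile,
                 compartment_contrast = compartment_contrast,
                 block_width = as.integer(block_width),
                 loops = loops, seed = as.integer(seed)),
            class = "synthetic_hic_params")
}

#' Treatment perturbation applied to the generative model
#'
#' Encodes the treated condition relative to untreated: compartment contrast
#' multiplied by `gamma_comp` where both bins fall in a cluster region, and
#' loop enrichment multiplied by `gamma_intra` / `gamma_inter` according to
#' the loop's truth class. All gains equal to 1 reproduce the untreated model.
#'
#' @param clusters data frame (`chrom`, `start`, `end`) of cluster regions,
#'   0-based half-open bp coordinates; may be NULL.
#' @param gamma_comp,gamma_intra,gamma_inter non-negative gain factors.
#' @export
perturbation_spec <- function(clusters = NULL, gamma_comp = 1,
                              gamma_intra = 1, gamma_inter = 1) {
  stopifnot(gamma_comp >= 0, gamma_intra >= 0, gamma_inter >= 0)
  if (!is.null(clusters)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(clusters)),
              all(clusters$start < clusters$end))
  }
  structure(list(clusters = clusters, gamma_comp = gamma_comp,
                 gamma_intra = gamma_intra, gamma_inter = gamma_inter),
            class = "perturbation_spec")
}

# classify injected loops by cluster membership of their anchor bins:
# both anchors in (the same) cluster -> intra; exactly one -> inter;
# neither -> background.
classify_loop_truth <- function(loops, clusters, bin_size) {
  if (is.null(loops) || nrow(loops) == 0) {
    return(cbind(loops, data.frame(class = character(0))))
  }
  cls <- character(nrow(loops))
  for (k in seq_len(nrow(loops))) {
    mid1 <- (loops$a1[k] + 0.5) * bin_size
    mid2 <- (loops$a2[k] + 0.5) * bin_size
    c1 <- c2 <- NA_integer_
    if (!is.null(clusters)) {
      cl_rows <- which(clusters$chrom == loops$chrom[k])
      h1 <- cl_rows[clusters$start[cl_rows] <= mid1 &
                      mid1 < clusters$end[cl_rows]]
      h2 <- cl_rows[clusters$start[cl_rows] <= mid2 &
                      mid2 < clusters$end[cl_rows]]
      if (length(h1)) c1 <- h1[1]
      if (length(h2)) c2 <- h2[1]
    }
    cls[k] <- if (!is.na(c1) && !is.na(c2) && c1 == c2) "intra" else
      if (!is.na(c1) || !is.na(c2)) "inter" else "background"
  }
  loops$class <- cls
  loops
}

# Poisson mean matrix (full symmetric) for one chromosome and one condition
contact_mu <- function(n, bin_size, chrom, params, perturb, treated) {
  s <- params$compartment_profile
  if (is.null(s)) s <- make_compartment_profile(n, params$block_width)
  stopifnot(length(s) >= n)
  s <- s[seq_len(n)]
  alpha <- params$decay_exponent
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- (1 + d)^(-alpha)

  cc <- params$compartment_contrast
  C <- matrix(cc, n, n)
  if (treated && !is.null(perturb$clusters) && perturb$gamma_comp != 1) {
    cl <- perturb$clusters[perturb$clusters$chrom == chrom, , drop = FALSE]
    inside <- rep(FALSE, n)
    for (k in seq_len(nrow(cl))) {
      idx <- bins_overlapping(cl$start[k], cl$end[k], bin_size, n)
      inside[idx] <- TRUE
    }
    C[inside, inside] <- cc * perturb$gamma_comp
  }
  comp <- 1 + C * outer(s, s)
  if (any(comp < 0)) stop("compartment contrast produces negative means; reject parameters")
  mu <- mu * comp

  loops <- params$loops
  if (!is.null(loops) && nrow(loops) > 0) {
    loops <- loops[loops$chrom == chrom, , drop = FALSE]
    if (nrow(loops) > 0) {
      cls <- classify_loop_truth(loops, perturb$clusters, bin_size)$class
      i <- row(mu); j <- col(mu)
      for (k in seq_len(nrow(loops))) {
        L <- loops$L[k]
        if (treated) {
          L <- L * switch(cls[k], intra = perturb$gamma_intra,
                          inter = perturb$gamma_inter, 1)
        }
        a1 <- loops$a1[k] + 1L; a2 <- loops$a2[k] + 1L; w <- loops$w[k]
        # symmetric bump at (a1, a2) and its mirror
        g <- exp(-((i - a1)^2 + (j - a2)^2) / (2 * w^2)) +
          exp(-((i - a2)^2 + (j - a1)^2) / (2 * w^2))
        mu <- mu * (1 + L * pmin(g, 1))
      }
    }
  }
  # scale so expected upper-triangle total equals depth
  k_scale <- params$depth / sum(mu[upper.tri(mu, diag = TRUE)])
  mu * k_scale
}

# draw one symmetric count matrix from its mean matrix
draw_contact_matrix <- function(mu, chrom, bin_size, seed) {
  n <- nrow(mu)
  ut <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[ut] <- with_seed(seed, stats::rpois(sum(ut), mu[ut]))
  counts <- counts + t(counts) - diag(diag(counts), n)
  contact_matrix(counts, chrom, bin_size)
}

#' Simulate one synthetic Hi-C contact map
#'
#' @param genome a [genome_spec()].
#' @param params a [synthetic_hic_params()].
#' @param perturb a [perturbation_spec()] (NULL = untreated model).
#' @param treated apply the perturbation gains.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return list of `contact_matrix`, one per chromosome.
#' @export
simulate_contact_map <- function(genome, params, perturb = NULL,
                                 treated = FALSE, seed = NULL) {
  if (is.null(perturb)) perturb <- perturbation_spec()
  if (is.null(seed)) seed <- params$seed
  check_perturb_in_genome(genome, perturb)
  out <- vector("list", length(genome$chroms))
  names(out) <- genome$chroms
  for (ci in seq_along(genome$chroms)) {
    n <- genome$n_bins[ci]
    mu <- contact_mu(n, genome$bin_size, genome$chroms[ci], params, perturb,
                     treated)
    out[[ci]] <- draw_contact_matrix(mu, genome$chroms[ci], genome$bin_size,
                                     seed + (ci - 1L) * 1000L)
  }
  out
}

check_perturb_in_genome <- function(genome, perturb) {
  cl <- perturb$clusters
  if (is.null(cl)) return(invisible(TRUE))
  for (k in seq_len(nrow(cl))) {
    ci <- match(cl$chrom[k], genome$chroms)
    if (is.na(ci)) stop("cluster on unknown chromosome: ", cl$chrom[k])
    if (cl$start[k] < 0 || cl$end[k] > genome$lengths[ci]) {
      stop("cluster outside chromosome bounds: ", cl$chrom[k])
    }
  }
  invisible(TRUE)
}

#' Simulate a paired untreated/treated Hi-C experiment with ground truth
#'
#' Draws the untreated model and the perturbed (treated) model with
#' independent derived seeds and returns the injected-object truth. With all
#' perturbation gains equal to 1 and `seeds = c(s, s)` the two draws are
#' identical cell-for-cell.
#'
#' @inheritParams simulate_contact_map
#' @param seeds length-2 seeds for the untreated and treated draw; default
#'   `c(params$seed, params$seed + 1)`.
#' @return list with `untreated`, `treated` (lists of `contact_matrix`) and
#'   `truth` (injected loop table with classes, per-bin compartment labels,
#'   cluster regions).
#' @export
simulate_contact_pair <- function(genome, params, perturb = NULL,
                                  seeds = NULL) {
  if (is.null(perturb)) perturb <- perturbation_spec()
  if (is.null(seeds)) seeds <- c(params$seed, params$seed + 1L)
  stopifnot(length(seeds) == 2)
  untreated <- simulate_contact_map(genome, params, perturb, treated = FALSE,
                                    seed = seeds[1])
  treated <- simulate_contact_map(genome, params, perturb, treated = TRUE,
                                  seed = seeds[2])
  comp_labels <- lapply(seq_along(genome$chroms), function(ci) {
    s <- params$compartment_profile
    if (is.null(s)) s <- make_compartment_profile(genome$n_bins[ci],
                                                  params$block_width)
    sign(s[seq_len(genome$n_bins[ci])])
  })
  names(comp_labels) <- genome$chroms
  loops <- params$loops
  if (!is.null(loops) && nrow(loops) > 0) {
    loops <- classify_loop_truth(loops, perturb$clusters, genome$bin_size)
  }
  list(untreated = untreated, treated = treated,
       truth = list(loops = loops, compartment_labels = comp_labels,
                    clusters = perturb$clusters,
                    gains = perturb[c("gamma_comp", "gamma_intra",
                                      "gamma_inter")]))
}

#' Place synthetic accessible-region peaks inside clusters
#'
#' Peaks are placed uniformly at random inside each cluster, non-overlapping
#' and avoiding gene-body intervals (mimicking regulatory, non-genic
#' accessible regions).
#'
#' @param genome a [genome_spec()].
#' @param clusters data frame (`chrom`, `start`, `end`); one row per cluster.
#' @param genes data frame (`chrom`, `start`, `end`) of gene bodies, or NULL.
#' @param n_per_cluster peaks per cluster.
#' @param peak_width peak width in bp.
#' @param seed RNG seed.
#' @return data frame `chrom, start, end, peak_id, cluster_id`.
#' @export
simulate_peaks <- function(genome, clusters, genes = NULL, n_per_cluster = 5L,
                           peak_width = 600L, seed = 1L) {
  check_perturb_in_genome(genome, perturbation_spec(clusters = clusters))
  if (n_per_cluster == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_id = character(0),
                      cluster_id = character(0)))
  }
  with_seed(seed, {
    out <- list()
    for (k in seq_len(nrow(clusters))) {
      cl <- clusters[k, ]
      cl_id <- if ("cluster_id" %in% names(clusters)) cl$cluster_id else
        sprintf("cluster_%d", k)
      g <- if (is.null(genes)) NULL else
        genes[genes$chrom == cl$chrom, , drop = FALSE]
      # quick feasibility: free space not covered by gene bodies
      free <- free_space(cl$start, cl$end, g)
      if (sum(pmax(free$end - free$start - peak_width + 1, 0)) < n_per_cluster) {
        stop(sprintf("cluster %s too crowded to place %d peaks", cl_id,
                     n_per_cluster))
      }
      placed <- data.frame(start = numeric(0), end = numeric(0))
      attempts <- 0L
      while (nrow(placed) < n_per_cluster) {
        attempts <- attempts + 1L
        if (attempts > 1000L * n_per_cluster) {
          stop(sprintf("cluster %s too crowded to place %d peaks", cl_id,
                       n_per_cluster))
        }
        st <- floor(stats::runif(1, cl$start, cl$end - peak_width))
        en <- st + peak_width
        if (!is.null(g) && nrow(g) > 0 &&
            any(intervals_overlap(st, en, g$start, g$end))) next
        if (nrow(placed) > 0 &&
            any(intervals_overlap(st, en, placed$start, placed$end))) next
        placed <- rbind(placed, data.frame(start = st, end = en))
      }
      placed <- placed[order(placed$start), , drop = FALSE]
      out[[k]] <- data.frame(chrom = cl$chrom, start = placed$start,
                             end = placed$end,
                             peak_id = sprintf("%s_peak_%d", cl_id,
                                               seq_len(nrow(placed))),
                             cluster_id = cl_id)
    }
    do.call(rbind, out)
  })
}

# complement of gene bodies within [start, end)
free_space <- function(start, end, genes) {
  if (is.null(genes) || nrow(genes) == 0) {
    return(data.frame(start = start, end = end))
  }
  g <- genes[intervals_overlap(genes$start, genes$end, start, end), ,
             drop = FALSE]
  if (nrow(g) == 0) return(data.frame(start = start, end = end))
  g <- g[order(g$start), , drop = FALSE]
  segs <- data.frame(start = numeric(0), end = numeric(0))
  cur <- start
  for (k in seq_len(nrow(g))) {
    if (g$start[k] > cur) segs <- rbind(segs, data.frame(start = cur,
                                                         end = g$start[k]))
    cur <- max(cur, g$end[k])
  }
  if (cur < end) segs <- rbind(segs, data.frame(start = cur, end = end))
  segs$start <- pmax(segs$start, start)
  segs$end <- pmin(segs$end, end)
  segs[segs$end > segs$start, , drop = FALSE]
}

#' Truth-labelled synthetic gene set
#'
#' Assigns each gene an induction class per stimulus (IFN type A / type B),
#' an induction magnitude (`extreme` log2FC ~ 6, `moderate` ~ 3), an
#' ISGF3-dependence flag (accessibility lost in the knockout) and a
#' homeostatic flag (expression and accessibility down in the knockout
#' without stimulation).
#'
#' @param n_genes number of genes.
#' @param p_induced_a,p_induced_b,p_shared class probabilities (shared genes
#'   are induced by both stimuli).
#' @param p_extreme fraction of induced genes with extreme induction.
#' @param p_isgf3 fraction of type-A-induced genes that are ISGF3-dependent
#'   (type-B induced genes use `p_isgf3_b`).
#' @param p_isgf3_b see above.
#' @param p_homeostatic fraction of genes with homeostatic ISGF3-dependent
#'   accessibility.
#' @param seed RNG seed.
#' @return data frame of per-gene truth flags.
#' @export
make_truth_genes <- function(n_genes = 400L, p_induced_a = 0.15,
                             p_induced_b = 0.15, p_shared = 0.1,
                             p_extreme = 0.3, p_isgf3 = 0.7,
                             p_isgf3_b = 0.35, p_homeostatic = 0.05,
                             seed = 1L) {
  with_seed(seed, {
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    u <- stats::runif(n_genes)
    class_ab <- ifelse(u < p_induced_a, "A_specific",
                ifelse(u < p_induced_a + p_induced_b, "B_specific",
                ifelse(u < p_induced_a + p_induced_b + p_shared, "shared",
                       "none")))
    induced_a <- class_ab %in% c("A_specific", "shared")
    induced_b <- class_ab %in% c("B_specific", "shared")
    magnitude <- ifelse(class_ab == "none", "none",
                        ifelse(stats::runif(n_genes) < p_extreme, "extreme",
                               "moderate"))
    isgf3 <- (induced_a & stats::runif(n_genes) < p_isgf3) |
      (!induced_a & induced_b & stats::runif(n_genes) < p_isgf3_b)
    homeostatic <- stats::runif(n_genes) < p_homeostatic
    # a gene whose homeostatic accessibility depends on ISGF3 loses its peak
    # in the knockout, so it is ISGF3-dependent by construction
    isgf3 <- isgf3 | homeostatic
    data.frame(gene_id = gene_id, class_ab = class_ab,
               induced_a = induced_a, induced_b = induced_b,
               magnitude = magnitude, isgf3_dependent = isgf3,
               homeostatic = homeostatic)
  })
}

#' Simulate differential expression/accessibility tables from gene truth
#'
#' Builds the six differential tables consumed by the integration rules:
#' RNA for stimulus A and B (treated vs untreated), RNA knockout vs wildtype,
#' and peak-level ATAC tables for both stimuli and the knockout contrast
#' (one synthetic promoter peak per gene, `<gene>_pk`). `log2FC` is Normal
#' around the class mean; adjusted p-values are uniform on `[0, 0.01]` for
#' non-null classes and uniform on `[0, 1]` for nulls.
#'
#' @param truth a [make_truth_genes()] table.
#' @param effect named list of class means: `extreme`, `moderate`, `atac_up`,
#'   `down`.
#' @param sd Gaussian noise sd on log2FC.
#' @param seed RNG seed.
#' @return named list of data frames (`rna_a`, `rna_b`, `rna_ko`, `atac_a`,
#'   `atac_b`, `atac_ko`), each with `id`, `log2FC`, `padj` (ATAC tables also
#'   carry `gene_id`).
#' @export
simulate_differential_tables <- function(truth,
                                         effect = list(extreme = 6,
                                                       moderate = 3,
                                                       atac_up = 3,
                                                       down = -3),
                                         sd = 0.1, seed = 1L) {
  needed <- c("extreme", "moderate", "atac_up", "down")
  if (!all(needed %in% names(effect))) {
    stop("missing effect-size class mean(s): ",
         paste(setdiff(needed, names(effect)), collapse = ", "))
  }
  n <- nrow(truth)
  if (n == 0) stop("empty truth table")
  with_seed(seed, {
    rna_mean <- function(ind) ifelse(ind & truth$magnitude == "extreme",
                                     effect$extreme,
                                     ifelse(ind, effect$moderate, 0))
    mk <- function(id, mu, non_null, extra = NULL) {
      tbl <- data.frame(id = id,
                        log2FC = stats::rnorm(n, mu, sd),
                        padj = ifelse(non_null, stats::runif(n, 0, 0.01),
                                      stats::runif(n, 0, 1)))
      if (!is.null(extra)) tbl <- cbind(tbl, extra)
      tbl
    }
    pk <- paste0(truth$gene_id, "_pk")
    gene_extra <- data.frame(gene_id = truth$gene_id)
    list(
      rna_a = mk(truth$gene_id, rna_mean(truth$induced_a), truth$induced_a),
      rna_b = mk(truth$gene_id, rna_mean(truth$induced_b), truth$induced_b),
      rna_ko = mk(truth$gene_id,
                  ifelse(truth$homeostatic, effect$down, 0),
                  truth$homeostatic),
      atac_a = mk(pk, ifelse(truth$induced_a, effect$atac_up, 0),
                  truth$induced_a, gene_extra),
      atac_b = mk(pk, ifelse(truth$induced_b, effect$atac_up, 0),
                  truth$induced_b, gene_extra),
      atac_ko = mk(pk,
                   ifelse(truth$isgf3_dependent | truth$homeostatic,
                          effect$down, 0),
                   truth$isgf3_dependent | truth$homeostatic, gene_extra)
    )
  })
}
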