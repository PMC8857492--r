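# shared fixture builders; everything is generated in code at test time

# small symmetric count matrix with positive marginals
toy_counts <- function(n = 10, seed = 42, lambda = 5) {
  withr::with_seed(seed, {
    x <- matrix(stats::rpois(n * n, lambda), n, n)
    x <- x + t(x)
    diag(x) <- diag(x) + 1  # keep marginals positive
    x
  })
}

toy_matrix <- function(n = 10, seed = 42, bin_size = 10000L, ...) {
  contact_matrix(toy_counts(n, seed, ...), chrom = "chr1",
                 bin_size = bin_size)
}

# Toeplitz matrix with value v[d + 1] on diagonal d
toeplitz_matrix <- function(v, bin_size = 10000L) {
  n <- length(v)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  contact_matrix(matrix(v[d + 1], n, n), chrom = "chr1", bin_size = bin_size)
}

# balanced matrix ready for O/E-based analyses
prep_matrix <- function(m, q = 0.02) ice_balance(mask_low_coverage(m, q))

# one checkerboard simulation at the compartment scale
sim_checkerboard <- function(seed, n = 200, bin_size = 40000L, depth = 5e5,
                             contrast = 0.4, block = 20L) {
  g <- genome_spec("chr1", n * bin_size, bin_size)
  p <- synthetic_hic_params(depth = depth, compartment_contrast = contrast,
                            block_width = block, seed = seed)
  simulate_contact_map(g, p)[[1]]
}
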