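# ifn3d

Quantitative analysis of interferon (IFN)-induced 3D chromatin
reorganization at interferon-stimulated gene (ISG) clusters.

Type I and type II interferon stimulation remodels the nuclear organization
of macrophage genomes within hours: ISG clusters gain A-compartment
strength, short-range intra-cluster chromatin loops intensify while
longer-range inter-cluster contacts weaken, accessible regulatory regions
inside the clusters interact more strongly than distance-matched controls,
and the accessibility gains at type I IFN targets largely require the
ISGF3 transcription-factor complex (STAT1/STAT2/IRF9). `ifn3d` implements
the quantitative core of that analysis as a tested R package for anyone
integrating paired-condition Hi-C with ATAC-seq/RNA-seq differential
tables, together with a synthetic data generator with known ground truth
so every statistic can be validated end to end.

## What it computes

* **Contact-matrix model** (`contact_matrix`): symmetric binned cis maps
  with low-coverage masking, ICE balancing (iterative correction to equal
  row sums), distance-decay expected profile E(d), observed-over-expected
  (O/E) maps, replicate merging, exact multinomial subsampling and log2
  ratio maps. Matrices read/write a sparse TSV dialect
  (`#chrom  bin_size  n_bins` header, then `bin_i  bin_j  count`, i <= j).
* **Replicate similarity** (`scc`): the stratum-adjusted correlation
  coefficient — 2D mean-filter smoothing, per-distance-stratum Pearson
  correlations r_k combined with weights w_k = N_k sd1_k sd2_k.
* **A/B compartments** (`compute_compartment_track`): eigendecomposition of
  O/E − 1 over unmasked bins, eigenvector chosen among the top three by
  correlation with an activity track (RNA-seq coverage), sign-phased so
  positive = A, scaled by sqrt(|eigenvalue|). Saddle plots and the
  compartmentalization strength (AA + BB) / (2 AB)
  (`saddle_strength`); region-versus-control ΔPC1 statistics with
  size-matched intervals 1 Mb up-/downstream (`delta_pc1_regions`) and the
  Wilcoxon rank-sum test (`rank_sum_test`).
* **Chromatin loops** (`score_map`, `detect_loops`, `quantify_loops`):
  template correlation of a standardized Gaussian-dot kernel with local
  windows of log(1 + O/E), loop calls as thresholded local maxima
  (score > 0.35), per-condition quantification after subsampling every
  condition to the smallest contact total, inter-/intra-cluster
  classification with the median score ratio (`classify_cluster_loops`),
  and Spearman score reproducibility (`loop_score_correlation`).
* **Regulatory-region interactions** (`cluster_pair_strengths`,
  `paired_enrichment_test`): mean balanced contact between all
  within-cluster pairs of non-genic accessible peaks, compared with two
  constructed control pairs per real pair — same midpoint distance, sizes
  swapped, placed up-/downstream — using the Wilcoxon signed-rank test.
* **RNA/ATAC integration** (`classify_type_specific`,
  `select_induced_groups`, `annotate_peaks_to_genes`,
  `classify_accessibility_dependence`, `chi_square_2x2`): IFN-type-specific
  induction calls (log2FC >= 1, padj <= 0.05 in one type, log2FC < 1 in the
  other), extreme/moderate induction strata (log2FC > 5 vs 1–5), top-200
  selection, nearest-TSS peak annotation, and the ISGF3-dependence
  classification with its 2x2 chi-squared comparison between IFN types.
* **Synthetic truth** (`simulate_contact_pair`, `simulate_peaks`,
  `make_truth_genes`, `simulate_differential_tables`): paired-condition
  Hi-C maps with power-law decay (1 + d)^(−α), checkerboard compartments,
  injected Gaussian dot loops and Poisson counting noise; perturbation
  gains γ_comp, γ_intra, γ_inter encode the treatment effects; matched
  peaks and truth-labelled differential tables.

## Worked example

The `analysis/` directory is a numbered end-to-end study over the bundled
synthetic generator. Running

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_replicate_similarity.R
Rscript analysis/03_compartments.R
Rscript analysis/04_loops.R
Rscript analysis/05_regulatory_interactions.R
Rscript analysis/06_integration.R
```

writes tables under `results/` and prints (seed 1):

```
within-condition SCC 0.988/0.992, between conditions 0.935
phasing: eigenvector 1 (untreated, r = 0.977), 1 (treated, r = 0.978)
saddle strength: untreated 2.047, treated 2.080
clusters with delta-PC1 above both controls: 5/5
rank-sum cluster vs control means: W = 50, p = 0.00067
fusion map: 15 calls above 0.35; 15/18 injected loops recovered
untreated inter/intra score ratios: isg_cluster_1 = 0.823, isg_cluster_2 = 0.903, isg_cluster_3 = 0.773
treated inter/intra score ratios: isg_cluster_1 = 0.607, isg_cluster_2 = 0.673, isg_cluster_3 = 0.558
paired signed-rank over 18 pairs (0 dropped): V = 135, p = 0.0304
median interaction strength: real 0.0175 vs control 0.0089
agreement with truth labels: 100.0%
published table: X2 = 142.56, p = 7.32e-33 (reported as p = 2.2e-16 floor)
```

Reading the output: replicates of the same condition are near-identical by
SCC while conditions differ; the treated condition raises ΔPC1 above both
distance-matched controls in every perturbed cluster (rank-sum p < 0.001);
the inter/intra loop-score ratio drops in every cluster after treatment
(the signature of intra-cluster loop gain with inter-cluster loss); real
regulatory peak pairs interact about twice as strongly as their
distance-matched controls; and the classification rules recover the
generator's truth labels exactly. The single run of `run_pipeline()` wraps
the same stages behind one seeded, manifest-checksummed call.

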