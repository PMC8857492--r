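---
title: "Models and methods behind ifn3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ifn3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifn3d)
```

`ifn3d` quantifies how interferon stimulation reorganizes chromatin at
interferon-stimulated gene (ISG) clusters: compartment-strength changes,
loop-score shifts, regulatory-region interaction enrichment, and the
integration of differential expression with differential accessibility.
This vignette explains the models, the tunable parameters and their
defaults, the synthetic generator used for validation, and the design
decisions taken where more than one reasonable choice existed.

## Contact-matrix model and normalization

A `contact_matrix` holds one chromosome's symmetric binned cis map of raw
counts. Bin `i` (0-based) covers `[i * bin_size, (i + 1) * bin_size)`; all
genomic coordinates in the package are 0-based half-open. Analyses are
cis-only and per-chromosome; genome-level summaries aggregate over
chromosomes. Cross-chromosome (trans) contacts are out of scope.

Low-coverage bins are masked before balancing: a bin is excluded when its
marginal count is zero or below the `q`-quantile of the nonzero marginals
(`mask_low_coverage`, default `q = 0.02`). Balancing is plain ICE —
iterative correction of per-bin weights until the coefficient of variation
of unmasked row sums falls below `tol` (default `1e-6`), with weights
scaled so the mean balanced row sum is 1. ICE was chosen over
Knight–Ruiz-style scaling because the convergence criterion is explicit
and directly testable; non-convergence raises an error carrying the final
CV rather than returning a half-balanced map.

The expected profile `E(d)` is the mean balanced value over unmasked cells
at bin distance `d`, and the observed-over-expected map divides each cell
by `E` at its distance, which forces every unmasked diagonal of O/E to
mean 1 — an identity the tests assert to `1e-9`.

Subsampling to a target contact total (`subsample_counts`) draws the
upper-triangle cells from one multinomial, so the result hits the target
exactly, stays symmetric, and each cell is marginally binomial — the
property the coverage-equalization step of loop quantification relies on.
Contact totals count the upper triangle including the diagonal, i.e. each
contact once.

## Replicate similarity (SCC)

`scc` smooths both raw maps with an edge-truncated `(2h+1)^2` mean filter
(default `h = 1`; masked cells are excluded from window means rather than
padded), computes the Pearson correlation `r_d` of paired entries in each
genomic-distance stratum, and combines strata as
`scc = sum(w_d r_d) / sum(w_d)` with `w_d = N_d * sd1_d * sd2_d`. Defaults
follow common replicate-QC practice for this assay: 10 kb bins and a 1 Mb
maximum scanning distance. Strata run from `d = 1` to
`max_distance / bin_size`; the `d = 0` diagonal is excluded because in
real libraries it is dominated by self-ligation artifacts and would
inflate similarity. Strata with zero variance in either map carry weight
zero, and the self-comparison returns exactly 1.

## Compartments

The compartment score is an eigenvector of the mean-centered O/E matrix
(`O/E − 1`) over unmasked bins. Among the first three eigenvectors (by
eigenvalue magnitude) the one correlating most strongly with a per-bin
activity track — RNA-seq coverage in practice — is selected, sign-flipped
so the correlation is positive (positive PC1 = A compartment), and scaled
by the square root of its eigenvalue magnitude.

Two choices deserve comment. First, the classic alternative
eigendecomposes the Pearson *correlation* matrix of O/E rows; it is
available via `method = "correlation"`, but it is not the default because
the row-wise unit-variance normalization discards amplitude. A treatment
that strengthens compartmentalization inside a cluster changes mostly the
*amplitude* of the compartment signal there, which is precisely what the
ΔPC1 statistic measures; on synthetic data the correlation variant
recovers the injected direction in barely half the clusters while the
mean-centered O/E variant recovers essentially all of them. Second, the
sqrt-eigenvalue scaling keeps between-condition PC1 differences
meaningful: a unit-norm eigenvector would renormalize away genuine global
strength changes. A `phase_correlation` below 0.3 flags the call as
degenerate (no usable compartment signal), which is what happens on
compartment-free decay-only maps.

Saddle analysis ranks scored bins into `n_quantiles = 10` equal-occupancy
groups and averages O/E over group pairs (same-bin cells excluded). The
compartmentalization strength is `(mean AA + mean BB) / (2 mean AB)` over
the corner blocks spanning `corner_fraction = 0.2` of the groups — the
common convention; both knobs are exposed.

ΔPC1 statistics use 40 kb bins. For each region the mean of
`PC1_treated − PC1_untreated` is taken over all bins whose interval
intersects the region (any overlap counts), and compared against two
size-matched controls whose starts sit 1 Mb up- and downstream of the
region start. Controls that would extend beyond the chromosome are
dropped and flagged, never shortened — size matching is the point of the
construction. Region-level means for perturbed versus control regions are
compared with the unpaired Wilcoxon rank-sum test (exact for combined
n ≤ 20 without ties, normal approximation with tie correction otherwise);
per-region paired controls are also emitted for inspection.

## Loops

Loop scoring slides a dot-shaped template over `log(1 + O/E)` and reports
the Pearson correlation between template and local window. The template
(`loop_kernel`) is a centered 2D Gaussian (sd 1.5 bins) minus its mean,
standardized to unit variance — 17x17 at 10 kb, 9x9 at 5 kb. It is a
deliberately simple, fully specified stand-in for the dot templates used
by sliding-template detectors; the log transform stabilizes the dynamic
range so that scores are invariant under positive scaling of the counts
(asserted to `1e-9` in the tests). Windows need at least 80% valid
(in-bounds, unmasked) cells, otherwise the cell scores NA; zero-variance
windows are NA as well, so a featureless flat map yields no scores at all.

Detection keeps cells above the score threshold (default 0.35, the same
cutoff used for reporting) that are local maxima among their eight
neighbours, then greedily suppresses calls within 3 bins Chebyshev
distance of a better call. Quantification follows the fusion-map design:
positions are detected once on the sum of all conditions/replicates, each
condition is subsampled to the smallest total, re-masked, re-balanced, and
scored only at those positions, making scores comparable across
conditions. Scanning runs between `min_d = 50 kb` and `max_d = 10 Mb`.

Cluster statistics consider loops with at least one anchor midpoint in a
cluster and an anchor-midpoint separation below 500 kb: both anchors in
the same cluster is intra, exactly one (or anchors in two different
clusters) is inter, and the per-cluster summary is
`median(inter) / median(intra)`. No score filter is applied by default for
these statistics (`min_score = NULL`); the display threshold can be
switched on via `min_score = 0.35`. Reproducibility is the Spearman rank
correlation of per-loop scores between samples, over shared loops with
defined scores (at least 3 required).

## Regulatory-region interactions

Accessible peaks are restricted to those intersecting a cluster and
intersecting no gene body (gene-body peaks tend to be broad and
uninformative for regulatory elements). For each within-cluster pair A–B
(B downstream), the real interaction strength is the mean balanced value
over all bin pairs covered by the two peaks — balanced, not O/E, matching
an interaction-strength readout on normalized matrices; an O/E variant is
a one-line change but not the default. Two controls accompany each pair:
an interval of B's size whose midpoint lies the pair's midpoint distance
upstream of A (paired with A), and an interval of A's size the same
distance downstream of B (paired with B). Midpoint-to-midpoint distance
is used because it makes the conservation property exact in integer
arithmetic: intervals are placed by center with half-open rounding toward
the start on odd sizes, so every valid control preserves the real pair's
distance to the base pair. Controls outside the chromosome are flagged
invalid; a pair with no valid control is dropped (and counted).

Real-versus-control differences (control = mean of the valid controls)
are tested with the two-sided Wilcoxon signed-rank test, exact for
n ≤ 25, normal approximation with zero-difference exclusion otherwise.
The unpaired rank-sum test remains available, but the paired design is
the default: each real pair carries its own distance-matched null.

## RNA/ATAC integration rules

All rules consume differential tables (id, log2FC, adjusted p-value);
multiple-testing correction happens upstream and is never recomputed.
Defaults: significance means `padj <= 0.05`, induction means
`log2FC >= 1`, extreme induction `log2FC > 5`, moderate `1 <= log2FC <= 5`.
A gene is type-specific when significantly up in one stimulation and below
the induction threshold in the other; up in both is shared. The top-200
selection takes the 200 largest significant log2FC values with ties broken
by gene id (deterministic); fewer than 200 available returns all with a
warning. Peaks annotate to the gene with the nearest TSS (start on +,
end on −; ties to the smaller gene id).

ISGF3 dependence: a gene is "induced-accessible" (red) when RNA-up under
stimulation and at least one annotated peak is ATAC-up under the same
stimulation; it is ISGF3-dependent (blue) when additionally some annotated
peak loses accessibility significantly (`log2FC <= −1`) in the Irf9
knockout. The `log2FC <= −1` sign is used for all knockout-down rules even
where a source legend prints the threshold without the minus sign — the
symmetric reading is the only consistent one. "Any annotated peak" is the
default quantifier; "all" is available. The 2x2 comparison of dependent
versus independent loci between the two IFN types uses Pearson's
chi-squared with 1 df and no Yates correction (the counts involved are in
the hundreds, where the correction only biases).

## The synthetic generator

`simulate_contact_pair` draws each upper-triangle cell independently as
Poisson with mean

```
mu_ij = k * (1 + |i − j|)^(−alpha) * (1 + c_ij * s_i * s_j) *
        prod_loops (1 + L * g_ij)
```

where `alpha` is the decay exponent (default 1), `s` a per-bin compartment
profile (default alternating ±1 blocks of 20 bins), `c` the checkerboard
contrast (default 0.4), `g_ij` a Gaussian bump of width `w` bins at the
loop anchors (capped at 1 so the anchor cell is enriched exactly
`1 + L`-fold), and `k` set so the expected upper-triangle total equals the
configured depth. The treated condition multiplies `c` by `gamma_comp`
where both bins lie in a cluster and the loop enrichment by `gamma_intra`
or `gamma_inter` according to the loop's truth class; all gains at 1
reproduce the untreated law exactly, which the determinism test exploits
(same seed, identical pair). Untreated and treated draws use distinct
derived seeds by default so that a gains-at-1 pair is a genuine null
replicate for calibration studies. Poisson (rather than negative-binomial)
noise is sufficient for the rank- and correlation-based statistics
downstream; swapping in overdispersion is a single change in the draw.

Study conditions were fixed once, guided by the scale of the real system:
ISG clusters span roughly 0.5–2 Mb, so the compartment arm uses a 10 Mb
chromosome at 40 kb with five 560 kb clusters placed inside A blocks and a
merged-replicate coverage of 4e6 contacts (two replicates of 2e6 — about
what ~500M genome-wide contacts provide per 10 Mb); the loop arm uses a
2 Mb chromosome at 10 kb, three 300 kb clusters, injected dots with
`L = 5, w = 2` at 5e5 contacts. Null-calibration studies run 400 reduced
replicates (190 bins at 5e5 for ΔPC1; 150 bins at 1e5 for the control-pair
test) so that the full suite stays fast.

What the generator does *not* emulate bounds what passing tests show:
there are no translocation/assembly artifacts, no copy-number or
restriction-fragment structure, no replicate batch effects, no
overdispersion beyond Poisson, no TAD-scale insulation, and loops sit on a
homogeneous decay background. Recovery rates on this generator therefore
demonstrate the correctness and calibration of the statistics, not their
field performance on real libraries.

## Numerical choices and degenerate inputs

* ICE raises on non-convergence (reporting the final CV) and on unmasked
  zero-marginal bins; all-masked inputs are errors, not empty results.
* O/E cells whose expected value is zero while the observed is positive
  raise; zero-over-zero is NA. In the eigendecomposition, O/E entries at
  distances with no data carry no signal and enter as 0 after centering.
* Rank-based tests switch between exact and approximate regimes at the
  conventional sizes (20 combined / 25 pairs) and return `p = 1` with a
  degeneracy flag when every value (or every difference) is identical.
* Detection is deterministic: candidate maxima are ordered by score, ties
  resolved by position, and suppression uses Chebyshev distance.
* Region/bin overlap uses "any intersection counts"; truncated ΔPC1
  controls are dropped, not shortened.
* Peak placement is rejection sampling with a feasibility pre-check, so an
  over-crowded cluster fails with the cluster's name instead of looping.

## Limitations

The package analyses one chromosome per object and cis contacts only;
trans-based compartment calling, TAD/insulation analysis, other template
shapes (borders, hairpins), flexible 2D binning for ratio maps, and
upstream processing (alignment, peak calling, differential model fitting)
are out of scope. The saddle and SCC implementations target the moderate
matrix sizes of per-chromosome analyses (up to a few thousand bins);
nothing is optimized for whole-genome single-matrix workflows.
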