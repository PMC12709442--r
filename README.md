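# transpoloop

Clustered transposon insertion and chromatin unfolding: genomic
statistics plus a coarse-grained polymer model of the feedback between
the two.

Transposons make up a large fraction of eukaryotic genomes and occur in
clusters. Insertion of a transposon can locally decompact chromatin, and
decompacted chromatin is more accessible to the transposases that insert
further transposons — a positive feedback that can concentrate new
insertions next to old ones. `transpoloop` is for researchers in
chromatin biophysics and repeat genomics who want to (a) quantify
clustering, open-chromatin association and sequence-inherent flexibility
of annotated repeat elements, and (b) simulate under which biophysical
conditions clustered insertion emerges in a folded chromatin domain.

## What is inside

**Genomic statistics** (tibble-in / tibble-out, pipe-friendly):

* pairwise center-distance distributions against the closed-form density
  for uniform placement, `p(x) = 2 (L - x) / L^2`, on log bins;
* 1-D DBSCAN cluster calling on element centers
  (eps = 10,000 nt, min_samples = 2) with per-chromosome in-cluster
  fractions and cluster span statistics;
* overlap of (clustered vs. isolated) elements with open-chromatin peak
  tracks, Mann-Whitney U group comparisons;
* TRX dinucleotide flexibility scores for sequences, regions and
  subfamilies, with flexibility-accessibility and flexibility-age
  (chronological rank) regressions.

**Polymer model**: a self-attracting bead-spring chromatin domain
(`Ntot` beads of 3 kb / 30 nm; harmonic bonds; Kratky-Porod bending with
a ~90 nm persistence length; WCA repulsion; native-native
Lennard-Jones attraction of 1.5 kBT, cutoff 2.5 sigma) evolved by
Langevin dynamics (Rcpp core). Transposon insertion converts attractive
"native" beads into purely repulsive "transposed" beads, either at a
prescribed chain adjacency `alpha` or emerging from explicit diffusing
transposase particles whose effective size `s_t` controls their
exclusion from dense chromatin and whose rate `k_t` sets the insertion
attempt interval (`1000 / k_t` timesteps). Unfolding is quantified by
the radius of gyration `Rg(Ntr)`, Hill fits
`Rg = R0 + (Rinf - R0) Ntr^n / (K^n + Ntr^n)` (exponent `n` =
sharpness, `K` = transition point), the maximum-likelihood placement
adjacency `alpha_mle` of an insertion history, radial insertion
metrics, core-shell classification, and replicated `(k_t, s_t)` scans.

**Synthetic data**: generators for clustered (Neyman-Scott) and uniform
element placements, open-chromatin tracks with controllable coupling to
clusters, Markov-chain sequences with controlled dinucleotide content,
and pure lattice insertion histories — the fixtures behind every
statistical test in the suite.

See the methods vignette (`vignettes/transpoloop-methods.Rmd`) for the
model, its assumptions, parameter choices and limitations.

## Worked example

Clustering analysis on synthetic annotations:

```r
library(transpoloop)
library(dplyr)

genome  <- synth_genome("chr1", 5e7)
repeats <- synth_clustered_annotations(genome, n_elements = 600,
                                       cluster_intensity = 0.4,
                                       cluster_spread = 4000,
                                       clustered_fraction = 0.8, seed = 42)
called <- cluster_elements(repeats, eps = 10000, min_samples = 2)
cluster_stats(called)$summary
#> # A tibble: 1 × 4
#>   n_clusters mean_span max_span fraction_in_clusters
#>        <int>     <dbl>    <dbl>                <dbl>
#> 1         25    15760.    25576                0.828

reference <- uniform_reference(repeats, seed = 43)
mean(cluster_elements(reference)$in_cluster)
#> [1] 0.24
```

83% of the clustered synthetic elements fall into DBSCAN clusters
(25 clusters, mean span ~16 kb) versus 24% for length-matched uniform
reference elements at the same density — the clustering signature the
pipeline is built to detect.

Unfolding under fully adjacent insertion (`alpha = 1`, scaled-down
chain of 50 beads, 10,000-step segments):

```r
set.seed(44)
p   <- sim_params(n_monomers = 50, eps = 2.0)
run <- run_prescribed(p, alpha = 1, segment_steps = 10000)
glance(fit_hill(run))
#> # A tibble: 1 × 7
#>      r0 r_inf     n     k resid_norm converged n_obs
#>   <dbl> <dbl> <dbl> <dbl>      <dbl> <lgl>     <int>
#> 1  1.84  7.59  1.67  25.2       4.61 TRUE         51

alpha_mle(run)
#> [1] 1
```

The chain unfolds from a globule (`Rg ~ 1.8 sigma`) to a coil
(`~7.6 sigma`) with a small Hill exponent (`n = 1.7`): adjacent
insertion grows a loop and unfolding is gradual. Random insertion
(`alpha = 0`) instead gives a sharp, switch-like transition with Hill
exponents an order of magnitude larger, and the likelihood estimator
recovers the adjacency that generated the history (`alpha_mle = 1`).

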