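---
title: "Methods: polymer models and genomic statistics of clustered transposon insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polymer models and genomic statistics of clustered transposon insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transpoloop)
```

# Scope

`transpoloop` studies a feedback loop: transposon insertion locally
decompacts chromatin, and decompacted chromatin is more accessible to the
transposases that insert further transposons. The package has two halves
that meet in the middle:

* **Genomic statistics** quantify how strongly annotated repeat elements
  cluster along the genome, whether clusters coincide with open
  chromatin, and whether transposon sequences encode unusual DNA
  flexibility (TRX dinucleotide scores).
* **A coarse-grained polymer model** asks under which biophysical
  conditions clustered insertion *emerges*: a self-attracting chromatin
  domain unfolds as insertions convert attractive (native) beads into
  purely repulsive (transposed) beads, and explicit transposase
  particles decide where insertions land.

Everything is testable on synthetic data; a generator layer produces
clustered/uniform placements, open-chromatin tracks, sequences with
controlled dinucleotide content, and pure lattice insertion histories
under stated distributions and seeds.

# The polymer model

## Chain and units

The chromatin domain is a bead-spring chain of `Ntot` monomers (default
100). Each bead represents 3 kb of chromatin with an effective diameter
of sigma = 30 nm, an implied linear packing density of 100 bp/nm —
`packing_density_bp_per_nm()` — consistent with experimental estimates
of 90–130 bp/nm for interphase fibers. Internally the model uses reduced
units (sigma = 1, kBT = 1, monomer mass = 1); lengths convert to
nanometers by multiplying with `sigma_nm`.

Potentials:

* **Bonds**: harmonic, `U = k_bond/2 (r - sigma)^2` with
  `k_bond = 200 kBT/sigma^2`. The value is not dictated by the mapped
  biology; it is chosen stiff enough that bond-length fluctuations stay
  small (equipartition gives variance `kBT/k_bond`) while remaining
  stable at the default timestep.
* **Bending**: Kratky-Porod, `U = kappa (1 - cos theta)` with
  `kappa = 3 kBT`. For stiff chains the persistence length is
  approximately `kappa/kBT` bonds; with excluded volume the measured
  decay of tangent correlations gives ~2.5–3 bonds, i.e. 75–90 nm,
  matching experimental estimates of 50–200 nm. This is *verified* by
  the persistence-length property test, not assumed.
* **Repulsion**: Weeks-Chandler-Andersen (Lennard-Jones shifted up by
  `eps_rep` and truncated at its minimum `2^(1/6) d_eff`) between all
  particle pairs.
* **Attraction**: native-native pairs additionally feel a
  shifted-truncated Lennard-Jones attraction with cutoff `2.5 sigma`
  and strength `eps = 1.5 kBT` (well depth ~0.98 eps), enough to
  collapse the chain into a globule. `eps = 2.0 kBT` is supported and
  used where a crisper unfolding illustration is wanted; the comparative
  alpha = 0 vs alpha = 1 study in the test-suite uses 2.0 for exactly
  that reason.
* **Transposases** are free particles of effective diameter
  `s_t * sigma`. The repulsion cutoff for any pair involving a
  transposase is `2^(1/6) * s_t * sigma` — *smaller* than the mean pair
  diameter — so smaller transposases approach monomers more closely.
  This one knob encodes size-based exclusion from dense chromatin.

## Integration, thermostat, boundary

Dynamics are Langevin, integrated with BAOAB velocity Verlet at
`dt = 0.01 tau` and damping `gamma = 1/tau` (neither is dictated by the
mapped biology; both are chosen for stability and efficient diffusive
exploration). With the thermostat off the scheme reduces to plain
velocity Verlet and conserves energy to ~1e-4 relative drift over 1e4
steps, which the tests use as a force-consistency audit alongside a
direct finite-difference check of every force term. A reflecting sphere
of radius `r_bound` (default `max(15, Ntot/(2 pi))` sigma) confines all
particles; transposases are (re)injected on this boundary.

Simulations start with a soft push-off phase (a bounded cosine pair
potential ramped from 0 to 60 kBT replaces the hard potentials, removing
the overlaps of the random-walk initial chain), then equilibrate under
the full potential. After push-off no pair sits below 0.8 of its
repulsion cutoff (~0.9 sigma for monomers): separations below that mark
unresolved overlaps several kBT up the repulsive wall, whereas demanding
more would trip over ordinary thermal fluctuations. Equilibration warns
if the radius of gyration still trends (slope t-test, 95%) over the
second half of the phase.

## Insertion processes

**Prescribed adjacency** (`run_prescribed()`): one insertion per segment
of `segment_steps` timesteps (the full-scale protocol is 100,000-step
segments, one per insertion). With probability `alpha` the next
converted monomer is drawn uniformly from the native sites chain-adjacent
to an existing transposed site (uniform over all native sites when none
exists, e.g. at the first insertion), otherwise uniformly over all
native sites. Conversion flips the bead type only — positions and
velocities are untouched. The site choice never reads the spatial
configuration, which the tests verify by comparing adjacency counts
against pure lattice histories.

**Emergent insertion** (`run_emergent()`): transposases diffuse in from
the boundary; every `segment_length(k_t) = 1000/k_t` timesteps, native
monomers within the capture radius of a transposase convert, and the
spent transposases are recycled to the boundary (count conserved).
The capture radius defaults to the monomer-transposase contact distance
`(1 + s_t) sigma / 2`; the alternative `(1 + s_t) sigma` sits behind the
`rule` argument. Matching is one-to-one (greedy nearest, ties to the
lower monomer index), so distinct transposases can convert distinct
monomers in one insertion phase but no monomer converts twice.

Under the contact rule the capture shell — between the
monomer-transposase repulsion cutoff `2^(1/6) s_t sigma` and the capture
radius — closes as `s_t` approaches `1/(2^(7/6) - 1) ~ 0.80`, beyond
which capture would require climbing hundreds of kBT up the repulsive
wall. The physically meaningful transposase sizes for this model are
therefore `s_t` below ~0.8; mapping 30 nm beads to protein diameters of
5–20 nm gives the same range (`s_t` ~ 0.17–0.67). Scans in this package
use `s_t` in [0.2, 0.8] and insertion rates `k_t` in [0.1, 10] (the
stated rate range, i.e. 100–10,000 timesteps per segment).

## Outcome estimators

* `radius_of_gyration()`: RMS distance of chromatin monomers from their
  centroid; equal to the pair-sum identity, which the tests assert.
* `fit_hill()`: bounded Levenberg-Marquardt fit of
  `Rg(N) = R0 + (Rinf - R0) N^n / (K^n + N^n)`, multi-started from 5
  initializations (`n` in (0, 50], `K` in (0, Ntot]); all four
  parameters are free, since fixing baselines is not obviously justified
  for traces that plateau late. Non-convergence is reported in a flag,
  never as an error. The exponent `n` measures unfolding sharpness, `K`
  the transition point.
* `alpha_mle()`: maximum-likelihood placement adjacency of an observed
  insertion history under the prescribed-adjacency choice rule, using
  the first 50 insertions by default; maximized on a 1001-point grid
  with golden-section refinement, and cross-checked in the tests against
  exhaustive 1e-4-grid maximization. Events with no adjacent candidate
  are alpha-independent and drop out.
* `insertion_distance_metric()`: mean distance of the first 30 converted
  monomers from the chromatin center of mass, normalized by the
  instantaneous radius of gyration at the insertion frame. "Polymer
  center" means the center of mass of *all* chromatin monomers at that
  frame; a native-only center was considered and rejected as
  discontinuous late in a run (it can jump when few native monomers
  remain).
* `core_shell_classify()`: the polymer core is the sphere around the
  native centroid with 40% of the native bounding radius; transposed
  monomers inside coat a core-shell configuration, outside they form
  loops.
* `run_scan()` / `aggregate_scan()`: replicated (k_t, s_t) scans reduced
  to per-cell means and SDs of the estimators, with exact replicate
  bookkeeping. In scans the estimator windows scale with chain length
  (alpha over the first 50% of insertions, distance over the first 30%),
  which reproduces the full-scale windows of 50 and 30 events at
  `Ntot = 100` and keeps the windows meaningful for shorter chains.
* `scenario_label()`: descriptive quadrant labels (I: permeating
  transposases + slow insertion, core-shell unfolding; II: size
  exclusion + slow insertion; III: permeating + fast; IV: exclusion +
  fast, typically one prominent loop). Thresholds default to grid
  midpoints and are reported with the labels; they are presentation, not
  science.

## Problem sizes

Full-scale runs (Ntot = 100, 100,000-step segments, 25 replicates per
scan cell) are supported by the same code but take hours. The package's
own studies — the test-suite and the reproduction script — use a
documented scaled-down configuration: Ntot = 50, 10,000-step segments
and >= 10 replicates for the prescribed-model contrast, and a 2x2
(k_t, s_t) grid for the emergent scan with per-cell segment caps chosen
so nearly all runs convert most of the chain. The persistence-length
calibration uses the full Ntot = 100 chain (it is cheap because the
attraction is off).

# Genomic statistics

## Clustering of repeat elements

Element centers, `floor((start + end)/2)` in 0-based half-open (BED)
coordinates, drive everything. Pairwise center distances are computed
within chromosomes only and compared against the closed-form density for
uniformly placed points on a range of length `L`,
`p(x) = 2 (L - x) / L^2`, on logarithmically spaced bins (clustering
shows up as excess short-distance mass). For reference tracks, each
element is re-placed uniformly on the genomic range covered by the
elements of its chromosome, preserving lengths (`uniform_reference()`;
a pooled-genome variant sits behind a flag, per-chromosome is the
default since element density differs between chromosomes).

Clusters are called by 1-D DBSCAN on centers (eps = 10,000 nt,
min_samples = 2, per chromosome); for min_samples = 2 this equals the
transitive closure of the "within eps" relation with singletons as
noise, which is the brute-force oracle the tests compare against.
Cluster spans use element starts/ends, not centers, so element lengths
enter only the span. Open-chromatin peak tables are filtered to
high-confidence peaks (both assays, or combined p < 0.01) and overlap
fractions are computed per chromosome in interval or center mode,
separately for clustered and non-clustered elements; group differences
use the two-sided Mann-Whitney U test with midranks.

## DNA flexibility (TRX)

TRX scores assign each dinucleotide step the percentage frequency with
which it adopts the flexible BII phosphate conformation; a table has 10
free values (6 complement pairs, 4 self-complementary steps) and is
expanded to all 16 keys under enforced complement symmetry, making
sequence scores invariant under reverse complementation (asserted on
random sequences). A sequence scores the mean over its steps; steps
containing non-ACGT symbols are skipped; steps spanning interval
boundaries are excluded. Per-subfamily summaries average per-element
scores (each element counts once); a step-pooled alternative is
available. The shipped table (`trx_table_synthetic.tsv`) is a
**synthetic stand-in** with the documented structure and plausible
ordering (CG/CA-type steps flexible, AT the stiffest), because the
measured NMR scale is not redistributable here; every test uses an
explicit toy table, and real-sequence analyses should substitute the
published scale. Flexibility-accessibility and flexibility-age trends
are ordinary least squares (slope t-tests); "age" is consumed as a
chronological rank column, never computed.

# The synthetic-data generators

The generators define the study conditions for every statistical claim
in the test-suite:

* `synth_uniform_annotations()`: centers i.i.d. uniform per chromosome
  (chromosome picked proportional to size); elements may overlap — the
  uniform reference construction does not forbid it.
* `synth_clustered_annotations()`: a Neyman-Scott process — Poisson
  cluster centers (`cluster_intensity` per Mb), Gaussian offsets
  (`cluster_spread`), and a `clustered_fraction` mixture with uniform
  placement. Two interpretable knobs (how many clusters, how tight)
  cover what the clustering pipeline needs; no attempt is made to mimic
  repeat sequence evolution, fragmentation ages or real ideograms.
* `synth_open_chromatin()`: peaks track cluster intervals with
  probability `coupling`, else uniform; `coupling = 0` is the null for
  overlap comparisons, larger values create the clustered-elements-in-
  open-chromatin signature.
* `synth_sequences()`: first-order Markov chains over A/C/G/T with
  transition weights proportional to requested dinucleotide weights —
  sufficient because TRX is a dinucleotide statistic.
* `synth_insertion_history()`: the pure lattice adjacency process (no
  dynamics); the estimator recovery studies rest on it.

What passing tests on these fixtures shows — and what it does not: the
pipeline detects clustering, coupling and composition differences of the
kinds it is built for, at the effect sizes the generators produce. Real
repeat annotations add fragmented elements, chromosome-scale density
gradients, assembly artifacts and correlated peak calls that no test
here emulates; conclusions about real genomes need the real inputs,
consumed through the same readers.

# Numerical choices and degenerate inputs

* Zero pairwise distances (identical centers) go to the smallest log
  bin, since log-spaced edges exclude zero.
* The uniform-placement goodness-of-fit in the acceptance suite pairs
  elements disjointly (1,000 independent distances from 2,000 elements)
  because the full multiset of ~2e6 pairwise distances is strongly
  correlated (each element participates in 1,999 pairs), which inflates
  a naive chi-squared statistic far beyond its nominal distribution;
  disjoint pairs make the test exact. Bins with expected counts below 5
  are pooled.
* `alpha_mle` returns `NA` (flagged) when every event is
  alpha-independent; `fit_hill` returns a non-converged result rather
  than throwing; empty particle groups yield empty histograms with a
  recorded flag; a chain with no native monomers left classifies all
  transposed monomers as outside the core, with a warning.
* Transposase masses scale with volume (`s_t^3`) but are floored at 0.5
  so very small transposases do not force a smaller timestep; in the
  overdamped regime the mass only rescales the velocity distribution.
* DBSCAN neighborhoods are closed (`<= eps`), matching the standard
  implementation conventions.

# Known limitations

* The emergent model's capture rule makes `s_t` beyond ~0.8
  non-insertive by construction (see above); scans stay below that.
* At the scaled-down chain length the adjacency signal of the emergent
  model is weak — a 50-bead globule is mostly surface — so scan trends
  need replicate averaging and are inherently noisier than at full
  scale.
* The model is agnostic to the molecular cause of transposase exclusion
  (steric vs. interaction-based), ignores hydrodynamics, nucleosome-
  scale structure, transposon silencing/removal, and source-site
  dynamics of cut-and-paste transposition.
* TRX periodicity (~10 bp phasing) is out of scope; compartment labels
  are consumed, never inferred.
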