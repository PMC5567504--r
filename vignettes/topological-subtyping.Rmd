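---
title: "Topological subtyping of clinical cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological subtyping of clinical cohorts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topophen)
```

`topophen` stratifies a clinical cohort into subtypes with a Mapper-style
topological analysis of a small clinical feature matrix, and validates the
subtypes against resting-state functional connectomes with graph-theoretic
measures. This vignette explains the model behind each stage, the tunable
parameters and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the method leaves room.

## 1. The subject-space model

### Reference normalization

Each subject is a row of a matrix `M` over six clinical features: three
symptom scores (ADHD index, inattentive, hyperactive/impulsive) and three IQ
scores (full-scale, verbal, performance). Features live on different scales,
so all are z-scored against the typically-developing control (TDC) group:

$$\hat M_{ij} = \frac{M_{ij} - \mu_j^{\mathrm{TDC}}}{\sigma_j^{\mathrm{TDC}}}$$

`fit_reference_normalization()` computes `mu` and `sigma` from the reference
rows only, using the **population** SD (divide by `N`, not `N - 1`): the
reference cohort is treated as the distribution patients are measured
against, not as a sample from it. With a reference of one subject, or a
feature with zero spread in the reference, normalization is undefined and
the fit errors naming the offending feature. Z-scoring is invertible
(`denormalize_features()`), and is deliberately not idempotent: re-fitting
on already-normalized data gives a different (standardized) reference.

### Distance, lens, and the Mapper cover

Subject dissimilarity is the plain Euclidean distance over the six z-scored
features. The lens (filter) is the L-infinity centrality

$$f_\alpha = \max_\beta D_{\alpha\beta},$$

the distance from subject `alpha` to the farthest other subject. Under this
lens, subjects at the periphery of the point cloud take extreme values, so
the tips of Mapper branches collect the clinically most extreme subjects —
the property the peripheral-subject selection exploits. The lens is strictly
one-dimensional and the whole subject-space pipeline is deterministic: no
random number is drawn anywhere between the phenotype table and the flare
table.

`build_mapper()` covers the lens range with `n_intervals` equal-width
intervals, each widened symmetrically so that adjacent intervals share
`overlap_frac` of their final width (the conventional Mapper "gain"
parametrization: extension `e = p w / (2 (1 - p))` per side for base width
`w`). Subjects inside each interval are clustered by single linkage on the
restricted distance matrix. The cutoff uses the classic first-gap heuristic:
a histogram with `cluster_bins` bins spanning from the smallest merge height
to the diameter of the interval's preimage (diameter included as a datum) is
scanned for its first empty bin; the tree is cut in that gap, and if no bin
is empty the preimage stays one cluster. Including the diameter in the
histogram matters: a histogram over merge heights alone finds spurious gaps
in every Gaussian preimage and shatters the graph into singletons. Nodes are
the clusters; two nodes are joined exactly when they share a subject (the
nerve of the cover), with the shared count as edge weight.

### Cover defaults

The defaults are `n_intervals = 4`, `overlap_frac = 0.5`,
`cluster_bins = 5`. These were chosen by characterizing the pipeline on
synthetic three-group cohorts of 120 subjects across a grid of covers
(4–14 intervals, overlap 0.3–0.6, 5–10 bins): fine covers leave each
interval with fewer than ~10 subjects, where the gap heuristic cannot
distinguish sampling noise from real separation — satellite singleton nodes
then inflate node degrees, manufacture spurious junctions, and fragment the
graph — while 4 intervals at 50% overlap keep interval preimages at roughly
20–40 subjects and recover the planted three-branch topology in about 94%
of simulations. For cohorts much larger than a few hundred subjects,
`n_intervals` should grow roughly with the square root of the subject count
to keep preimages in that range; all three parameters are exposed in
`cover_config()`.

### Flares and peripheral subjects

`extract_flares()` operationalizes "branch": junction nodes are those with
degree at least 3; removing them splits the graph, and each remaining
connected component is one flare (a component with no junction — e.g. a
well-separated group forming its own chain — is a flare by itself). Flares
inherit the majority group label of their member subjects, with alphabetical
tie-break. `select_peripheral()` ranks a flare's members by lens value,
descending, ties broken by subject id, and returns the top `k` (default 15);
if the flare is smaller than `k` it returns everyone with a warning. These
two rules are a deterministic reading of a selection that, in the original
visual-analytics workflow, was partly done by eye; they are exact and
reproducible, which matters more for a tested pipeline than mimicking manual
curation.

## 2. The connectome arm

### From time courses to networks

`scrub()` removes exactly the frames whose framewise displacement (FD)
exceeds 1 mm — strictly greater than, so borderline frames at exactly 1 mm
survive, and no neighbouring frames are deleted. FD is consumed as an input
series (the preprocessed-repository convention); `fd_power()` can derive it
from six rigid-body parameters (rotations scaled by a 50 mm head radius) if
needed. `correlation_network()` is the Pearson matrix of the scrubbed
columns, erroring on zero-variance ROIs. Group-representative matrices are
elementwise means of raw correlations (`group_mean_network()`); Fisher-z
averaging is available behind a flag but is not the default, and averaging
always precedes positive thresholding.

### Positive-weight graph measures

Centralities and modularity operate on `positive_graph(R)`: negative edges
zeroed, diagonal removed. Strength is the weighted row sum. Betweenness
converts weights to lengths as `1/w` — stronger correlation, shorter path —
and reports unnormalized fractional path counts. PageRank is computed by
power iteration on the damped walk (`alpha = 0.85`) with uniform
redistribution from dangling nodes; it returns a probability vector to a
1e-12 L1 tolerance and errors, reporting the residual, if `max_iter` is
exhausted. Group-level nodal statistics are computed on per-subject graphs
(each subject's positive matrix), not on the group mean, because the
statistics layer models subject-level variability.

### Modularity and consensus

`modularity_score()` evaluates Newman's Q exactly; `louvain()` performs one
greedy optimization run. Because the underlying sweep order is
deterministic, the node order is shuffled by the run seed — this restores
the run-to-run variability that the consensus step integrates over.
`consensus_partition()` performs `n_runs` (default 1000) independent runs
and returns the partition with the highest mean normalized mutual
information (NMI) against all other runs, breaking ties by higher Q and then
lower seed. Identical partitions are deduplicated before the pairwise-NMI
pass, so the cost scales with the number of distinct local optima rather
than `n_runs^2`. NMI uses the arithmetic-mean entropy normalization by
default (geometric/min/max variants are flags); two single-module partitions
are identical and score 1, while an informative partition against a flat one
scores 0.

### Functional connectivity density

`fcd()` summarizes the **signed** correlation matrix against a module
assignment: intra-module FCD is the mean over unordered within-module pairs,
inter-module FCD the mean over cross pairs. Inter-module densities are
routinely negative, which is why FCD keeps signs while modularity and
centralities use only positive weights — the asymmetry is deliberate.
Modules of size one have no internal pair and report `NA`. FCD is linear:
the FCD of a group-mean matrix equals the mean of per-subject FCDs. In a
group comparison, the reference partition (typically the consensus partition
of one group's mean network) is fixed and applied to every subject via
`fcd_table()`.

## 3. The statistics layer

`anova_raw()` is the classical one-way F from sums of squares;
`anova_from_summary()` reconstructs the identical F from per-group
mean/SD/n, which reproduces any published summary table exactly when the
summaries match (`SS_within` uses sample SDs with `n - 1`). `ancova()`
compares nested linear models — covariates in both, group dummies only in
the full model — with age the default covariate; which covariates entered a
published analysis is often unstated, so the choice is recorded in the
result object. `bh_correct()` implements the Benjamini–Hochberg step-up rule
with standard monotone adjusted p-values; `bonferroni_posthoc()` runs
pooled-variance pairwise t-tests with the pair-count multiplier and reports
sign directions (`a>b`). `compare_groups()` chains the three: omnibus test
per measure, BH across the measure family, post-hocs for survivors. The two
natural families are the 15 FCD measures (5 intra + 10 inter for five
modules) and all ROIs within one centrality measure; the family is whatever
set of columns is passed in, and that choice is the user's to make
explicitly.

## 4. The synthetic-data generator

`gen_clinical_cohort()` draws the five free clinical features from a
multivariate normal per group: the two symptom subscales correlate at 0.5,
the three IQ scores at 0.6, symptoms and IQ are independent, and the ADHD
index is the exact sum of the two subscales — published group means satisfy
this identity to rounding, so the generator enforces it structurally. A
consequence worth knowing: the index SD is implied by the subscale SDs and
their correlation (about 3.5 for the control preset) rather than matching a
printed index SD; with the identity in place, both cannot be honoured at
once, and the identity was chosen because it is exact in the source
arithmetic. `cohort_presets()` carries the published three-group means and
SDs (15 per group as printed; 60/30/30 is the convention used for
topology-recovery simulations, since the true subgroup sizes behind a
published peripheral selection are unknowable).

`gen_modular_timeseries()` draws frames i.i.d. from a block correlation
matrix: `intra_r[k]` within module `k`, `inter_r` across module pairs, unit
diagonal, validated positive semi-definite at construction (a pivoted
Cholesky tolerates the PSD-but-singular boundary). `noise_sd` scales the
marginal SD of every series without touching correlations, so empirical
block means converge to their targets as frames accumulate — the property
the recovery tests rely on. The default 232 frames matches a typical
preprocessed resting-state run. What is *not* emulated: temporal
autocorrelation, haemodynamics, physiological noise structure, and
spatially heterogeneous within-module correlations. A green recovery test
therefore establishes that the estimator chain (scrubbing, correlation,
thresholding, consensus clustering) recovers a planted stationary block
structure — not that it is robust to realistic BOLD dynamics.
`inject_motion()` adds Gaussian spikes to frames whose FD profile exceeds
the scrub threshold, so scrubbing can be shown to restore the clean
correlations exactly on the surviving frames.

The synthetic five-network layout (DMN/ECN/SN/VN/BGN over 90 ROIs, sizes
20/20/15/15/20) is a constructed fixture with generic ROI labels — it fixes
one documented modular world for simulations and is not an anatomical atlas
lookup.

## 5. Numerical choices and degenerate inputs

- Ties in peripheral ranking break by subject id; majority labels break
  alphabetically; consensus ties break by Q then seed. All are deterministic.
- A constant lens (all subjects identical) collapses the cover to a single
  interval containing everyone.
- Intervals with no subjects are skipped silently; one-subject preimages are
  single nodes.
- PSD validation uses an eigenvalue tolerance of -1e-10; correlation targets
  must satisfy |r| < 1 strictly.
- Scrubbing errors when fewer than 2 frames survive; correlation errors on
  zero-variance ROIs, naming them.
- PageRank convergence is an L1 tolerance of 1e-12 with a 1000-iteration cap.
- Seeded generators save and restore the caller's RNG state, so identical
  seed and spec give bit-identical output regardless of surrounding code.

## 6. Known limitations

- Flare extraction by degree-3 junctions is faithful to the branch notion
  but brittle on noisy topologies: satellite nodes can manufacture
  junctions. The coarse default cover mitigates this; visual inspection via
  `autoplot()` is still recommended before interpreting flares clinically.
- The subtyping arm assumes complete clinical data; rows with missing
  features must be dropped or imputed upstream.
- With three extremely well-separated groups the Mapper graph may split into
  three disconnected chains rather than a literal Y; the flare rule counts
  components without junctions as flares, so the subtype count is unchanged,
  but junction-based orderings are then lens-based.
- The statistics layer implements fixed-effects comparisons only: no mixed
  models, permutation tests, or effect-size machinery beyond directions.
- Consensus-by-NMI selects the most central observed partition; it does not
  construct a co-assignment consensus matrix and can only return a partition
  that some run produced.
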