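---
title: "Staging midbrain organoids against fetal tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging midbrain organoids against fetal tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbstage)
```

## The problem

iPSC-derived midbrain organoids are used as in-vitro models of human
midbrain development, and a recurring question is *how far along* a given
organoid is relative to fetal gestational age. `mbstage` implements a set of
quantitative staging procedures that compare organoids with fetal midbrain
tissue on two complementary axes:

* **spatial organization** — on Visium-style spot lattices, which cell types
  sit next to which, summarized as a *niche pair profile*, and how similar
  that organization is between samples;
* **developmental time** — pseudotime along reconstructed lineages,
  gene-module activation, and pseudobulk expression correlation.

Every stage is exercisable on synthetic data with known ground truth, so the
whole pipeline is testable end to end without external downloads.

## Spatial staging

### Niche pair profiles

Each spot is labeled with the cell type an external deconvolution estimates
to be most abundant there (`label_spots()`; ties are flagged and broken by
declared type order, all-zero spots become `"unassigned"`). Lattice
adjacency is geometric (`build_adjacency()`): two spots are neighbors when
their center distance is at most 1.05 times the minimum pitch, which on a
regular hexagonal lattice yields the six lattice neighbors and tolerates a
couple of percent of jitter.

`count_neighbor_pairs()` counts, over all adjacency edges, the unordered
pair of endpoint labels. Three conventions are deliberate and configurable:

* **diagonal pairs are counted** — homotypic niches (a progenitor zone, a
  dopaminergic field) are informative structure, and dropping them would be
  the surprising choice;
* **normalization is by total retained edges**, making the profile a
  composition and hence comparable between samples of different sizes —
  required when organoid discs meet larger tissue sections;
* **edges touching unassigned spots are excluded from both numerator and
  denominator**, so missing labels do not distort frequencies.

### Similarity and temporal alignment

Between-sample distances are Euclidean on the pair-frequency vectors over
the union pair basis; similarity is `S = 1 - D / max(D)` over off-diagonal
pairs, so the most dissimilar pair in the compared set scores exactly 0 and
identical samples score 1. This keeps `S` monotone in `-D` while placing all
values in [0, 1]. One consequence worth knowing: `S` is *relative to the
compared set* — adding or removing samples rescales it.

`temporal_alignment()` averages each organoid's similarity over the
replicates of every tissue timepoint (replicates are treated as repeated
measurements of one timepoint, so averaging happens at the similarity level,
not the profile level), normalizes those similarities to weights, and
reports the weighted average of the timepoints as the organoid's estimated
gestational age. The estimate therefore lives inside the tissue timepoint
range by construction and compresses toward the interior near the
endpoints: an organoid essentially identical to the youngest tissue still
receives small positive weights on older timepoints unless its similarity
to them is exactly 0. The recovery checks account for this by testing
monotonicity of the seed-averaged estimate in the known mixing weight and
the midpoint estimate under symmetric mixing, rather than exact endpoint
recovery.

### Maturation paths and spatial screening

`order_spots_on_polyline()` turns a hand-annotated polyline into an ordered
spot sequence (orthogonal projection, ordered by arc length; ties broken by
distance then spot id). `moving_average()` smooths expression along the
path with a centered window, **truncated** at the ends — padding would
fabricate data where the path stops. The default window of 50 spots matches
the scale at which such trends are usually summarized; note the centered
formulation uses `floor(w/2)` on each side, so an even target yields an odd
effective window.

`path_trend_test()` is a deliberately simple substitute for cell-type
decomposed differential expression along the path (which requires the
deconvolution model itself and is out of scope): Spearman correlation of
expression with path rank, with a permutation p-value (exhaustive for n ≤ 7,
otherwise sampled with the +1 correction). It answers "does this gene trend
along the path", not "in which cell type does it trend".

`morans_i()` uses binary neighbor weights without row standardization —
the simplest defensible convention, switchable — and a two-sided
permutation p centered at the null expectation `-1/(n-1)`.
`rank_pairs_by_moran()` screens per-spot score maps (for example the
neighbor ligand–receptor score `ligand(s) × mean receptor over neighbors`
from `neighbor_lr_score()`), ranks by I and adjusts p-values with
Benjamini–Hochberg. The neighbor score is a local co-occurrence measure; no
claim of equivalence to optimal-transport signaling inference is made.

## Lineages and pseudotime

`build_knn_graph()` (union kNN, Euclidean, deterministic index tie-break;
default k = 10) feeds `cluster_connectivity()`, which scores cluster pairs
by inter-cluster edges divided by the smaller cluster's total degree,
clipped to [0, 1]. This is a transparent substitute for published
graph-abstraction statistics: it is monotone in inter-cluster connectivity,
bounded, and exactly testable against enumeration. The pruning threshold of
0.05 is kept, with **strict** semantics: an edge at exactly 0.05 survives.

`prune_and_path()` takes the hop-count shortest path (the field's "shortest
path" on an abstraction graph), breaking ties by the largest minimum edge
weight along the path and then lexicographically, so results are
deterministic and oracle-checkable. A waypoint, when given, splits the
search into two legs whose concatenation is collapsed if a cluster repeats.
Roots, endpoints and waypoints are user parameters: cluster numbering is
dataset-specific and cannot be hard-coded.

HVG selection follows the intersect-then-union scheme: top-n genes per
replicate by a dispersion ranking of log-normalized values standardized
within 20 gene-mean bins; replicate sets are intersected within each
timepoint (robustness to replicate noise) and unioned across timepoints
(sensitivity to stage-specific variability). The scheme is monotone: adding
a timepoint can only grow the final set.

Pseudotime is the min–max rescaled first principal component of the
standardized log-normalized HVG matrix, sign-oriented so the root cluster
scores lowest, with an adjusted R² of PC1 on cell-type labels reported as a
sanity check that PC1 tracks identity progression. Diffusion pseudotime and
GAM-based trajectory tests are intentionally not reimplemented; the binned
start-vs-end call (`bin_profiles()`: 1st/99th percentile trimming, five
equal-width bins, permutation test on the last-minus-first bin mean at
p < 0.001 and |log2 FC| > 2) is named as a substitute in its output.
"Evenly spaced" bins are read as equal-width in pseudotime; equal-count
binning would weight cell density differently and is left to the caller via
the trimmed pseudotime itself.

## Module scores and group comparisons

A module's activation in a cell is the mean log-normalized expression of
its genes (`activation_score()`). Group comparisons use a two-sided one-way
permutation test with the absolute difference of group means as statistic —
the canonical two-sample choice where only the test family is conventional —
with the +1-corrected p, exhaustive enumeration when at most 10 cells are
compared, and, for unequal groups, resampling of the larger group to the
smaller group's size (100 times by default) with the mean p reported.
Benjamini–Hochberg adjustment is applied across modules to the mean p
(adjusting per resample and averaging afterwards would not yield valid
adjusted p-values). Sampled permutations draw from a sorted pool so the
result cannot depend on which group is labeled first.

`timepoint_profile()` summarizes per-group score distributions (mean, sd,
Gaussian kernel density with Silverman's bandwidth on a shared grid), and
`ranksum_compare()` wraps the Wilcoxon rank-sum test (exact for small
untied samples, otherwise the tie-corrected normal approximation without
continuity correction, matching the closed-form z statistic).

## Pseudobulk staging

`pseudobulk_means()` averages any per-cell value layer per group over a
gene set — log-normalized values by default; if a batch-corrected layer is
available it can be passed instead, and the layer used is recorded in the
result. Cross-dataset batch correction itself is out of scope.
`correlation_matrix()` is plain Pearson correlation between group profiles,
with constant profiles dropped; `correlation_hclust()` offers
average-linkage ordering for heatmaps as presentation, not analysis.

## The synthetic study

`synthetic_config()` defines the study conditions the package is built
around; the generator writes the same on-disk formats the readers accept,
so synthetic and real data share one code path.

* **Lattices.** Tissue sections are hexagonal patches of radius 8
  (217 spots); organoids are discs of radius 7 (169 spots). These sizes are
  small Visium capture areas — large enough that a niche pair profile over
  ~10 unordered type pairs is estimable with modest sampling noise, small
  enough that the whole study generates in seconds.
* **Composition.** Four cell types ordered from progenitor-like to mature
  (floor-plate progenitors through dopaminergic neurons). Spot mixtures are
  Dirichlet draws whose concentrations are tilted two ways: along the
  maturation coordinate (`gradient_strength = 3`, a ventricular-zone-like
  progenitor edge grading into a mature side) and by gestational age
  (`timepoint_shift = 1.2` over the 7–17 PCW range), so older tissue is
  mature-type-rich. The "deconvolution output" is the true mixture under
  multiplicative gamma noise (shape 50), emulating a good but imperfect
  deconvolution.
* **Organoids.** A disc with a progenitor core and mature periphery. The
  radial maturation coordinate is quantile-matched to the tissue's
  coordinate distribution (a raw radial coordinate would over-represent the
  periphery, because spot count grows with radius, and systematically
  "age" the organoid). The disc is composed of two contiguous angular
  sectors following the two parent tissues' age-tilted compositions, with
  the sector fraction equal to the mixing weight α and a random
  orientation: contiguity makes the *pair statistics* interpolate linearly
  in α (pair frequencies are quadratic in label proportions, so
  interpolating each spot's mixture pointwise biases the profile toward the
  younger tissue), while the random orientation keeps each spot's expected
  mixture at `(1-α)·A + α·B`. The implied age is `(1-α)·t_A + α·t_B`.
* **Counts.** Negative binomial (variance μ + μ²/θ, θ = 2) around
  mixture-weighted type signatures (markers at 8-fold enrichment), with a
  block of maturation-dependent genes (log-slope ±1.5 along the coordinate)
  and ~2000 counts per spot — shallow but Visium-plausible depth.
* **Single cells.** A latent pseudotime in [0, 1]; stage markers in three
  Gaussian bumps (early/mid/late), gene modules with configured log-effects
  (defaults 1.0 / 0.5 / 0, the zero module serving as a built-in null),
  extra monotone trend genes, and timepoint/replicate labels with later
  cells biased toward later timepoints so the HVG scheme and group
  comparisons are exercisable.
* **Determinism.** Every draw derives from one master seed through
  per-object sub-seeds, so any sample regenerates bit-identically in
  isolation.

What the generator does **not** emulate: segmentation/imaging artifacts,
spot swapping, realistic gene–gene covariance beyond modules, batch
effects, doublets, or the biological breadth of real annotations. Passing
tests therefore demonstrate that the *procedures* are implemented correctly
and recover known structure under their stated assumptions — not that real
organoids will align as cleanly.

## Numerical conventions

* Permutation p-values are never 0: sampled modes use
  `(1 + #extreme)/(1 + n_perm)`; exhaustive modes report the enumeration
  proportion (the identity permutation counts itself). The resampled group
  test keeps the +1 convention in both modes. `bin_profiles()` defaults to
  1999 permutations because its call threshold (p < 0.001) is unreachable
  below 999.
* Argmax ties in labeling and distance ties in kNN/path search always break
  deterministically (declared order, index, lexicographic ids).
* Entities with zero totals are kept as zero rows by `lognormalize()` with
  a warning — parsers and transforms do not make QC decisions.
* Degenerate inputs (constant fields, all-identical cells, disconnected
  lineages, all-zero similarities) raise classed errors rather than
  returning silently plausible numbers.

## Problem sizes used in the checks

The self-check report (`run_demo()`) runs 60 random-grid oracle
comparisons, 200 null simulations for each permutation calibration, 100
power simulations per effect size, 100 random path-oracle graphs, and
pseudotime recovery at 800 cells; the test suite repeats these at larger
scale (1000 grids, 500 null simulations, 1000 path graphs, 1000 cells ×
5 seeds). These sizes keep every run deterministic-given-seed and fast on a
single CPU while leaving the Monte-Carlo tolerances (±0.02 on rejection
rates, 1.5 PCW on midpoint recovery, 0.9 on pseudotime rank correlation)
comfortably testable.

## Known limitations

* Similarity is relative to the compared sample set; estimates are not
  comparable across runs with different sample rosters.
* The temporal estimator cannot extrapolate beyond the tissue timepoint
  range and compresses near its ends.
* PC1 pseudotime assumes the lineage's dominant expression axis is the
  maturation axis; strongly branched or cyclic structure violates this, and
  the adjusted R² check is a guard, not a proof.
* The neighbor ligand–receptor score and the path trend test are simple
  stand-ins for richer models, and are labeled as such in their outputs.

## A minimal run

```{r demo, eval = FALSE}
report <- run_demo(seed = 0, out = "report.json")
report$pipeline$alignment_pcw     # estimated PCW per organoid
report$all_pass                   # all self-checks
```
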