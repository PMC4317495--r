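---
title: "Methods: quantifying activation state-dependent adhesion complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying activation state-dependent adhesion complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesomics)
```

## The problem

Integrin receptors adopt active and inactive conformations, and the
adhesion complexes assembling around each conformation differ in
composition. Comparing the two complex proteomes by label-free
affinity-purification mass spectrometry raises a chain of analysis
questions: how to turn spectral counts into comparable abundances, how to
find groups of proteins with coherent activation state-dependent
recruitment, how those groups sit in the protein interaction network
around the bait integrin, which functions they are enriched for, and —
for the microtubule regulators that emerge from such an analysis — how to
quantify microtubule behaviour at the cell cortex. This package
implements that chain as composable, tested functions.

## Spectral-count quantification

A protein's normalized spectral count in one run is
`NSC = SpC / (T_s × M)`, where `SpC` is its unweighted spectral count,
`T_s` the total number of spectra observed in the whole run and `M` the
protein's molecular weight in kilodaltons. A fixed scale factor of 10^6 is
applied purely for readability: every downstream quantity (ratios,
correlations, cluster structure) is invariant to it. Technical replicates
are summed within each biological isolation and biological isolations are
then averaged per condition, so the reported value is the mean NSC of
biological duplicates.

Proteins enter the analysis only when their total unweighted spectral
count across all runs is at least four. The threshold could in principle
be read per sample or per condition; the total reading is the most
inclusive and is what `filter_min_count()` implements (the scope is a
parameter).

Fold enrichment is the active/inactive ratio of mean NSC. Proteins with a
zero mean in exactly one condition carry a `unique_active` /
`unique_inactive` status instead of a finite ratio — uniqueness is a
detection statement, not a ratio. For quantities that need a finite log2
fold change everywhere (cluster labelling, the enrichment map), zero
means are imputed with half the smallest non-zero mean NSC in the table,
a conventional floor that keeps unique proteins at the extremes of the
log2 scale without infinities.

### Differential flags

The original analysis used a hierarchical Bayesian spectral-count model
for differential abundance; its internals are out of scope here, so
`differential_flags()` fills the same role with an established
alternative: edgeR's negative-binomial exact test on the per-sample
counts, with each run's total spectra as its library size, followed by
Benjamini–Hochberg adjustment at 5% FDR. The negative-binomial form
matters: spectral counts are over-dispersed, and a Poisson-based test of
condition-summed counts (a G-test with library-size offsets, which we
evaluated first) is badly anti-conservative exactly when the data behave
like the generator below (empirical type-I ≈ 0.15 at nominal 0.05). The
exact test is calibrated under that over-dispersion and retains full
power at strong planted folds. One caveat for real data: the test treats
all runs as independent replicates, while technical duplicates are
correlated; summing technical replicates first is a stricter option.

## Profile clustering

Similarity between protein profiles is the uncentred Pearson correlation
`r = Σxy / √(Σx²·Σy²)` — a cosine similarity that, unlike centred
correlation, distinguishes a flat profile from an enriched one.
All-zero profiles are assigned `r = 0` against everything (the statistic
is undefined there, and "no similarity evidence" keeps the clustering
total). Trees are built by complete-linkage agglomeration on the distance
`d = 1 − r` and cut at `r ≥ 0.80`: clusters are the maximal subtrees all
of whose merge similarities reach the threshold, with singletons allowed.
Merges at exactly the threshold are included (union–find over the merge
list, rather than a strict height cut).

**Feature scale.** The clustering input is the per-condition,
per-biological-replicate summed NSC, on its natural scale. An earlier
design log-transformed these columns, but a log transform adds a large
common offset to every profile and drives all pairwise uncentred
correlations toward 1 (and, for profiles whose log values change sign,
produces spurious anti-correlation); the planted structure in synthetic
data became unrecoverable. On the raw scale a fourfold-enriched profile
points in a visibly different direction from a flat one and recovery is
essentially complete, so `profile_matrix()` defaults to no transform and
offers `log2` as an option.

**Labelling.** A cluster is active when its median log2 fold change
exceeds +0.58 (1.5-fold), inactive below −0.58, and unenriched inside the
band. The 1.5-fold value is the same enrichment threshold used by the
keyword overrepresentation filter, applied symmetrically; the original
figure does not state how the unenriched band was delimited, so this is
the package's own convention.

Ties in the agglomeration are resolved by the (deterministic) behaviour
of `stats::hclust`; on the continuous profiles clustered here exact ties
have probability zero, and the test suite verifies height-and-partition
agreement with a brute-force reference on tie-free random matrices.

## Interactome analysis

Edge lists from multiple sources are merged into one undirected simple
graph: reversed duplicates collapse, self-interactions are excluded, and
each edge remembers its sources. Paralogous subunits stay separate nodes.
Hop distances are breadth-first shortest-path counts from the seed
integrin (ITGB1 by convention); unreachable proteins are "not connected"
(`NA`). The candidate screen `neighborhood_intersection()` returns nodes
within a given radius of both of two protein sets (by default direct
neighbours), excluding the sets themselves. Identifier mapping between
accession and symbol namespaces is a preprocessing contract: a two-column
table applied before merging. Only degree, components and hops are
needed downstream, so no further topological statistics are computed.

## Overrepresentation and the enrichment map

For a query list of size `n` in a background of size `N`, a term with `K`
members and overlap `k` gets the one-sided Fisher p-value
`P(X ≥ k)` under the hypergeometric law, and the conservative EASE score —
the same tail with `k` reduced by one (`k ≤ 1` scores 1). Keyword-style
filtering requires fold enrichment `(k/n)/(K/N) ≥ 1.5`, Bonferroni
P `< 0.05` (corrected over the number of terms actually tested), EASE
`< 0.05` and `k ≥ 2`; the boundaries are inclusive for the fold and
strict for the p-values, as stated.

The resampling FDR follows the randomization protocol shape: 100 random
queries of the observed size are drawn uniformly from the background, all
term p-values recomputed, and a term's FDR is the expected number of
random discoveries at its p-value divided by the observed number, capped
at 1. It is deterministic given its seed.

The enrichment map is the matrix of passing terms (5–500 assigned
identified proteins) × proteins, filled with each protein's log2 fold
change where annotated and missing elsewhere. Term rows are clustered
with the same uncentred-Pearson/complete-linkage machinery; missing
entries are imputed as 0 — "no enrichment evidence" — for the distance
computation only and remain missing in the stored matrix. Terms are
clustered as rows; proteins keep their input order (the original figure
clusters terms).

## Cortical microtubule quantification

**Peripheral boxes.** The cell boundary polygon is tiled by arc length
into consecutive boxes, 5 μm along the edge and 2 μm inward along the
local normal; the final box may be shorter and is flagged. The original
boxes were drawn by hand; an inward-offset strip split every 5 μm is the
reproducible equivalent, with bisector normals at polygon vertices so
adjacent boxes share corner points. All geometric predicates are
boundary-inclusive — a microtubule touching a shared box border counts in
both boxes — which makes counts deterministic.

**Micropattern patches.** Ligand patches are 2 μm discs on a 9 μm square
lattice. Background is removed by grayscale opening with a flat disc
structuring element of the stated 50-pixel radius — the standard
practical equivalent of a rolling-ball filter (the implementation
rescales into the [0, 1] range EBImage's morphology expects and back).
Patch categories ("none" / "1–2" / "several") come from the number of
microtubule polylines entering each disc, available exactly in synthetic
mode.

**Residence.** The tip-to-edge distance is the per-frame Euclidean
distance to the nearest boundary point. The residence lifetime is the
*longest uninterrupted run* of frames within 2 μm of the edge times the
10 s frame interval — "remained within" is read as a single episode, not
cumulative time in the band (the cumulative reading is available by
summing runs, but is not the default). Growth excursions for the
displacement summaries are maximal runs of frame displacements above a
0.1 μm/frame pause threshold; the full comet-classification machinery of
dedicated tracking software (gap closing, turn-angle limits) is out of
scope, and the threshold preserves the "excluding shrinkage and pause"
intent.

## The synthetic generators

The generators define the study conditions under which the pipeline is
validated.

* `sim_counts()`: two conditions × 2 biological × 2 technical replicates
  of negative-binomial (gamma-Poisson) counts, `var = μ + φμ²` with
  default dispersion φ = 0.05 (≈26% CV at the default planted baseline of
  50 expected spectra — a realistic over-dispersion for spectral counts).
  Planted classes multiply the expected count by the planted fold in one
  condition; "unique" proteins have expected count zero in the other
  condition rather than post-hoc zeroed draws, matching detection-based
  uniqueness. Molecular weights are log-uniform over 10–300 kDa so the
  MW normalization is exercised across its dynamic range; per-sample
  total spectra are the realized column sums.
* `sim_interactome()`: exact-edge-count simple graphs; the scale-free
  model draws edges with Zipf fitness weights (heavier degree tail than
  the Erdős–Rényi reference at equal edge count), and the designated
  seed protein is the highest-fitness node.
* `sim_annotations()`: term sizes uniform in 5–500 (configurable),
  planted terms drawing a `purity` fraction of members from a named
  truth class.
* `sim_tracks()`: two-state tip dynamics — growth at 2 μm/frame toward
  the edge (≈12 μm/min, a typical interphase growth speed), geometric
  cortical dwell with regime-dependent mean (stimulatory > inhibitory by
  construction), catastrophe and re-nucleation at an interior point under
  the same microtubule id so per-id histories stay contiguous. Frames
  are 10 s apart.
* `sim_pattern_image()`: microtubule polylines rendered as Gaussian
  ridges over additive Gaussian noise, plus the 2 μm/9 μm patch lattice.

What these generators deliberately do *not* emulate: peptide-level
sampling and protein inference, correlated technical replicates, the
topology of the real curated interactome, the GO DAG's term nesting,
3-D geometry, and realistic microscope noise (only additive Gaussian).
Passing recovery tests therefore demonstrates the correctness and
calibration of the analysis chain under its stated assumptions, not
performance on raw instrument data.

## Problem sizes and seeds

The validation suite uses 2,000 proteins × 20 seeds for quantification
and clustering recovery, 1,000-protein backgrounds with 50 terms and 100
randomizations × 20 seeds for the FDR checks, 200 microtubules × 60
frames × 20 seeds per regime for residence recovery, and exhaustive
enumeration up to N = 25 for the hypergeometric oracle — sizes at which
every Monte-Carlo bound in the tests is stable while the full suite runs
in minutes on one CPU. Every stochastic function takes an explicit
integer seed and is byte-reproducible given it.

## Known limitations

* The differential test is a documented stand-in, not a reimplementation
  of the original hierarchical Bayesian model; flags on real data will
  differ in the tails.
* `adhesome_coverage()` and `class_summary()` take the inventory/roster
  as data; the curated adhesome itself is not shipped.
* Box tiling at concave vertices can produce self-overlapping corner
  boxes for boundaries with deep concavities at the 2 μm depth scale;
  counts remain well-defined (inclusive intersection) but corner boxes
  are then not disjoint.
* The rolling-ball filter is approximated by flat-disc grayscale opening;
  for smooth backgrounds the difference is negligible, for backgrounds
  curved at the ball scale it is not exact.
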