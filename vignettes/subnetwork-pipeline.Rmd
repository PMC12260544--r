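---
title: "Mapping, matching, and annotating individual-specific functional subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping, matching, and annotating individual-specific functional subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetr)
```

## The problem

Large-scale brain networks measured with resting-state functional
connectivity (RSFC) are not unitary: at sparser graph densities they break
into *subnetworks* — fine-scale communities nested inside each network —
and in deeply sampled individual subjects those subnetworks are reliable,
functionally distinct units. `subnetr` implements the full analysis chain
needed to study them without group averaging:

1. **Detect** fine-scale communities in a subject's dense Fisher-z
   connectivity matrix, after row/column density thresholding.
2. **Match** subnetworks across subjects by spatial overlap (Jaccard +
   iterative Louvain), keeping only clusters present in at least half of
   subjects, and summarize them as cross-subject density and
   winner-take-all maps.
3. **Annotate** each matched, spatially distributed subnetwork against a
   coordinate meta-analytic database (the Neurosynth layout: study
   activation peaks plus study-by-term weights), via multi-region study
   matching, per-term one-way ANOVA, and Benjamini–Hochberg FDR.
4. **Profile** subnetwork-to-network connectivity and task activation with
   repeated-measures ANOVA and paired post hoc t tests.
5. **Order** subnetwork signals in time with infraslow lag maps
   (cross-covariance with parabolic interpolation).

Because the motivating datasets (multi-hour per-subject fMRI plus the full
Neurosynth database) are far beyond desk scale, the package ships a
first-class synthetic-data module that generates every input with planted
ground truth. All statistical and recovery guarantees in the test suite
are statements about those planted conditions.

## The data model

A `node_space` carries node coordinates (mm), mesh adjacency, per-node
area (mm²) and a cortex/subcortex structure tag. A `timeseries` is a
node × time matrix with a sampling interval `tr` and run boundaries; a
`label_map` assigns a nonnegative integer label per node (0 = unassigned).
Everything reads and writes documented plain-text schemas (TSV matrices
and tables with JSON sidecars), which round-trip exactly for integer
labels and to better than 1e-6 for floats.

All coordinates in one analysis live in a single declared millimetre
space; distances are 3-D Euclidean (a geodesic metric on the cortical
sheet is out of scope). When an input format carries no geometry, node
areas default to 1 mm² with a warning.

## Connectivity and density thresholding

Connectivity is the Fisher transform `atanh(r)` of nodewise Pearson
correlations. Correlations are clipped to ±0.999999 before `atanh` so
duplicated signals produce a large finite z rather than infinity; constant
rows are reported as undefined (`NA`), never silently zeroed; the diagonal
is excluded from every density computation.

The sparsification rule keeps, for each row *and* each column, the top
fraction of entries: an entry survives if it is among the
`ceiling(density * (N - 1))` largest of its row *or* of its column, and
the kept mask is then symmetrized. The union reading preserves the
per-row retention guarantee the rule is stated with; ties at the cutoff
break by descending value then ascending partner index, so the output is
deterministic. The canonical operating point for dense cortical
connectomes is 0.1% (subnetwork tier), with denser tiers for large-scale
networks.

**Scale calibration.** The 0.1% figure presumes ~60k cortical vertices,
where it retains ~60 partners per row. On the 400-node synthetic grid the
same fraction keeps a single partner and every graph fragments, so the
synthetic-scale configuration (`synthetic_config()`) keeps an equivalent
neighborhood instead: 5% at the subnetwork tier (~20 partners). The
network tier obeys a capacity rule: the retained per-row neighborhood
`k = ceiling(d * (N - 1))` must not exceed the number of same-network
partners a node has (~132 on this grid, i.e. `d <= 0.33`). Past that
bound every node is *forced* to keep cross-network edges and the
community optimizer destabilizes — at `d = 0.35` Infomap intermittently
merges all networks, while any `d` in 0.25–0.30 recovers them exactly.
The default is 0.25.

## Community detection and the optimizer contract

Communities are detected on the thresholded binary graph with the map
equation (Infomap) by default, or multilevel modularity (Louvain) as a
pure-R-stack alternative; the two must and do agree (ARI ≥ 0.9) on
well-separated planted partitions, which is the contract the pipeline
relies on — its claims concern the thresholding tier and the matching
machinery, not one optimizer. Both are seeded and deterministic given the
seed. Communities smaller than `min_community_size` (default 10 nodes;
the sparse tier has no published minimum, so this is configurable) are
relabeled unassigned.

A subject's parent network is identified by maximal Jaccard overlap with
a template label map; the subnetworks of that network are the sparse-tier
communities with at least `overlap_fraction` (default 0.5 — "representation
within" the parent has no published number) of their nodes inside the
parent mask, kept at the ≥ boundary.

## Matching subnetworks across subjects

Every subnetwork instance of every subject enters a Jaccard overlap
matrix (within-subject pairs included; they are zero for disjoint
communities, so results are unaffected). Louvain runs on that weighted
graph iteratively — each round with a fresh seeded node order — until
modularity no longer increases over the previous round; clusters spanning
fewer than half of subjects are then discarded. Density maps count, per
node, the number of *individuals* whose matched subnetwork covers it (a
subject contributing two instances still counts once), and winner-take-all
maps assign each node to the cluster with the maximal count, breaking
ties deterministically by cluster order with an exported tie mask.

Two display thresholds follow the conventions they replicate: density
maps are shown at ≥ 3 subjects, while region extraction keeps vertices
covered in strictly more than 10% of subjects.

## Meta-analytic annotation of distributed subnetworks

Thresholded density maps are decomposed into connected regions under mesh
adjacency; regions not larger than 20 mm² are dropped. A study in the
database *matches* a subnetwork when it reports an activation peak
strictly closer than 2 mm to at least 40% of the subnetwork's regions
(`ceiling` of the fraction; distance is min over region nodes, since the
regions are spatial extents — a centroid-based reading is available
behind a flag). Matching is monotone in both parameters, which are
config-exposed for sensitivity sweeps.

For each curated term, the weights of the studies matched to each
subnetwork enter a one-way fixed-effects ANOVA; significant terms
(Benjamini–Hochberg FDR at 0.05 over all tested terms) are assigned to
the subnetwork with the largest mean weight (ties break to the
first-listed group, logged). The display magnitude — max group mean minus
grand mean — is presentation-only and never enters inference. A study
matching several subnetworks contributes to each group, with the
multi-match count logged. Term curation is data, not code: include and
exclude lexicons are supplied by the user.

## Profiling statistics

Subnetwork-to-network connectivity is the Fisher z of the correlation
between the subnetwork's mean time course and the target network's mean
time course, with overlapping nodes excluded from the target before
averaging. In short-distance exclusion mode the mean courses cannot be
pair-masked, so the profile is instead the mean z over node pairs farther
apart than 20 mm — both modes agree exactly when no pair is short.

The repeated-measures ANOVA is realized as a fixed-effects two-way
decomposition (level + subject block), which reproduces the classical
within-subject F; unbalanced tables are handled by omitting missing
subject × level cells from the sums of squares, and a level observed in
fewer than two subjects is dropped with a warning. Degenerate cases are
flagged rather than fabricated: zero between-level variance gives F = 0,
a zero residual (constant within-subject differences) gives F = Inf with
a `degenerate` flag. Bonferroni correction is `min(1, p * n_tests)` over
the declared family. Full mixed-model REML is deliberately out of scope.

Spring-graph export defines nodes as contiguous clusters larger than
20 mm², weights edges by the z of cluster mean time courses, keeps the
top 10% of edges, and raises the density in 5% increments whenever a
declared network is entirely disconnected from the giant component
(reaching density 1 without connection exports with a warning flag).
Negative edges stay in the statistics; the visualization convention of
dropping them is left to the renderer.

## Lag analysis

Signals are zero-phase bandpass filtered (Butterworth, forward–backward)
run by run — the filter never crosses a run boundary. The delay between
two signals is estimated from the cross-covariance at integer lags within
±8 s: the extremum of |cov| is located and a parabola through it and its
two neighbors gives the sub-frame delay (positive = second signal later).
Estimates are invalid — masked, not fabricated — when the extremum sits at
the window edge or the peak |r| falls below 0.1; anticorrelated pairs are
estimated at the |cov| peak with the sign recorded. Runs are combined by
frame-weighted averaging. Parabolic interpolation strictly reduces
quantization error relative to integer-lag argmax, a property the tests
assert.

A note on the passband: infraslow activity is conventionally defined as
< 0.1 Hz, but a 0.08–0.1 Hz reading is also in circulation for this
analysis. Both are selectable (`lag_band_hz`). The default is 0.01–0.1 Hz:
a 0.08–0.1 Hz signal is nearly sinusoidal with an ~11 s period, which
makes the cross-covariance extremum ambiguous inside an ±8 s search
window; the broad band keeps the extremum unique. Neither reading is
treated as a typo of the other.

Group ordering averages lag-map values over each structure's nodes, then
across the subject's seed maps, and centers each subject's structure
means (the zero point is arbitrary); a one-way ANOVA across structures
with subjects as observations tests for any ordering, followed by paired
post hoc t tests.

## The synthetic-data generator

`planted_design()` fixes the study conditions: a 20 × 20 planar grid
(6 mm spacing, 400 nodes, rook adjacency) tiled into 8 contiguous
subnetworks of 50 nodes nested in 3 networks (4 + 2 + 2); nested block
correlations 0.6 (within subnetwork) > 0.3 (within network) > 0.05
(background); 10% of nodes reassigned among neighboring labels per
subject to emulate topographic variability; 800–2000 frames at TR = 1 s
depending on the analysis; 500 studies × 250 terms with null weights
Uniform(0, 0.8) and planted associations shifting matched-group weights
by +0.2 (keeping all weights inside [0, 1]); signal lags carried by a
shared band-limited component delayed per structure by exact
frequency-domain (sinc) fractional shifts, over AR(1) node noise
(coefficient 0.3) at SNR 1 for lag studies. Gaussian signals are a
deliberate simplification — the pipeline only consumes correlations — and
a non-positive-definite covariance request is corrected by eigenvalue
flooring with a warning.

What the generator does *not* emulate: hemodynamic response shapes,
spatial autocorrelation of fMRI noise, heavy-tailed artifacts, geodesic
cortical geometry, and realistic database term co-occurrence. Passing
tests therefore demonstrate correctness of the machinery under the
planted model, not performance on real fMRI.

Problem sizes used by the test suite and the acceptance script — 400
nodes, 2000 frames and 20 seeds for detection; 10 subjects for matching;
500 studies × 250 terms × 20 seeds for annotation; 20 replicates plus a
15-subject ordering study for lags — were chosen as the smallest sizes at
which the planted effects are comfortably identifiable.

## Reproducibility and orchestration

Every stochastic step takes an explicit seed, and per-subject /
per-stream seeds derive deterministically from the base seed.
`run_pipeline()` runs any prefix of
`simulate -> detect -> match -> mana -> profile -> lag -> report` over an
output tree, writing exactly one `manifest.json` (command, resolved
config, input digests, seed, package version, timestamp) per stage
directory; a missing upstream output names the stage to run first. The
`report` stage collates cluster counts, significant terms, profile ANOVAs
and the temporal ordering into a single markdown summary. A thin CLI
(`inst/cli/subnets.R`) exposes the same stages from a shell.

```{r, eval = FALSE}
out <- tempfile("subnetr_run_")
run_pipeline(out, design = pipeline_design(rng_seed = 1),
             config = synthetic_config(rng_seed = 1))
readLines(file.path(out, "report", "report.md"))
```

## Known limitations

- Plain-text formats only; dense-connectome container formats (CIFTI-2 /
  GIFTI) are not parsed — inputs arrive through the documented TSV
  schemas.
- The subcortical question (whether subcortex enters the sparse-tier
  matrix or is assigned post hoc) is left to the caller via the
  `structure_tag` filter; the matching stage is cortex-first by design.
- The rotation-based null model used elsewhere to select the 0.1% tier is
  out of scope; the tier is taken as given.
- Consensus clustering across densities and force-directed layout are not
  implemented; graphs are exported for external rendering.
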