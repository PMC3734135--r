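---
title: "Voxel-based brain network analysis with voxnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based brain network analysis with voxnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`voxnet` analyses multi-session BOLD fMRI at the level of individual
gray-matter voxels. Each session becomes an undirected binary graph
whose nodes are gray-matter voxels and whose edges are suprathreshold
Pearson correlations between voxel time courses. Graphs are summarised
by degree and by global and local efficiency, mapped back into brain
space, compared across repeated sessions of the same cognitive state
(session-consistency maps, cross-subject meta maps), and tested for
state effects with two-condition × multi-session repeated-measures
ANOVAs on whole-brain and spherical-ROI metric means.

The pipeline assumes spatially aligned input (one common grid and
affine across sessions and masks). Motion realignment, normalization
and reslicing are out of scope; data are taken as they come from
standard realignment tools, together with the 6-column motion-parameter
text files those tools emit.

# Temporal preprocessing

Voxel time courses are extracted for every gray-mask voxel (columns
follow a linear x-fastest scan of the grid, and the node map records
the bijection node ↔ grid index ↔ mm coordinate through the affine).

**Band-pass filter.** The analysis band is 0.009–0.08 Hz, the
conventional low-frequency band for resting-state connectivity. The
filter is a zero-phase DFT mask: the series is transformed, every
Fourier bin with frequency outside `[low, high]` is zeroed, and the
series is inverse-transformed. We chose the DFT mask over a
forward–backward IIR filter because it has exactly unit pass-band gain
for periodic components, exactly removes DC (filtered series are
mean-zero), introduces no phase distortion, and applies to the whole
time × node matrix in two FFTs. Its trade-off is spectral leakage for
components that do not complete an integer number of cycles in the
window; the measured response on 240-sample probes retains ≥ 0.995 of
a 0.03 Hz sinusoid and passes < 1e-14 of DC or a 0.2 Hz sinusoid. The
filter type and band are recorded in the `filter` field of the result
so downstream metadata state what was actually applied.

**Nuisance regression.** Each voxel's filtered series is replaced by
its least-squares residual against an 11-column design: intercept, 6
motion parameters, and the mean global, white-matter and CSF signals
(the global signal is the mean over the union of all three tissue
masks; this choice is configurable). Regression follows filtering, and
by default the regressors are passed through the identical filter
first, so the projection acts within the analysis band — without this,
out-of-band regressor energy dilutes the fit; a flag disables it.
Motion-parameter derivatives are intentionally not included. The solve
is a pivoted QR; rank-deficient designs warn and drop dependent
columns, zero-variance voxels pass through as zero columns with a
warning, and residuals are orthogonal to every design column to
numerical precision, which also makes the operation idempotent.

# Network construction: the N = K^S density rule

All pairwise Pearson correlations are computed (blockwise for node
counts above a configurable limit, so the dense N × N matrix never
needs to exist at once). The binarization threshold is not a fixed
correlation value but the value that yields a prescribed connection
density: with N nodes and exponent S, the target mean degree is
K = N^(1/S), i.e. the threshold is the (1 − d*) quantile of the
off-diagonal correlations with d* = N^(1/S)/(N − 1). This keeps
density comparable across sessions and subjects even when N changes.
Results use S = 3.0 by default; S ∈ {2.5, 3.0, 3.5} is supported for
threshold-sensitivity checks.

Numerical conventions, chosen once and fixed:

* the target edge count is `floor(N · N^(1/S) / 2)` (K is a mean over
  integer degrees), with a 1e-8 guard against floating-point dips just
  below integer targets (e.g. `1000^(1/3)` evaluating under 10);
* thresholding is inclusive (`r ≥ r_th`) and applied to the *signed*
  correlation — the threshold is a lower bound, so strong negative
  correlations are excluded; an `absolute = TRUE` option thresholds
  |r| instead but is off by default;
* ties at the threshold are all included, so the realized K can exceed
  the target by the tie block; with continuous data the realized edge
  count equals the target exactly;
* edges are computed on the upper triangle and mirrored — symmetry and
  a zero diagonal hold by construction;
* zero-variance voxels correlate 0 with everything (with a warning)
  rather than propagating NaN.

# Graph metrics

Degree K(i) is the row sum of the adjacency. Nodal global efficiency
is

  E_glob(i) = (1/(N−1)) Σ_{j≠i} 1/d(i,j)

with d the unweighted shortest-path distance from breadth-first
search; unreachable pairs contribute 0, and no largest-component
extraction is performed (the density rule can leave isolated nodes,
and dropping them would silently change N). The network value is the
mean over all nodes, so it is consistent with the nodal map. Local
efficiency E_loc(i) is the global efficiency of the subgraph induced
on the neighbors of i (i itself excluded); nodes with fewer than two
neighbors get 0. This is the neighborhood-subgraph convention of the
standard brain-connectivity toolbox; note that some libraries (igraph)
instead route neighbor paths through the full graph minus the vertex,
which gives systematically larger values — the test suite demonstrates
the equivalence of our metric with induced-subgraph evaluation.
Clustering coefficient and characteristic path length are available as
optional metrics; the efficiency pair is primary because the two are
highly correlated in practice.

The traversals are implemented in C++ (Rcpp) over a compressed sparse
row adjacency; at the default problem size (≈1300 nodes, K ≈ 11) a
full session's metrics take well under a second, and all metrics equal
naive dense R oracles exactly (integers) or to 1e-12 (ratios) on
random graphs.

# Consistency mapping

For each subject, condition and metric, the top fraction of nodes
(default 20% for whole-brain maps) is marked in every session; the
session-consistency map is the per-voxel fraction of sessions in which
the voxel is marked. Ties at the rank cut are resolved
deterministically by (value descending, node index ascending), cutting
at exactly `ceiling(fraction · N)` nodes. Within-subject maps are
thresholded at ≥ 0.6 ("at least 3 of 5 sessions", implemented as an
inclusive fraction so it generalises to other session counts), and the
cross-subject meta map is the fraction of subjects whose thresholded
map contains the voxel.

For regional analyses the top 15% of nodes *within* an ROI (by local
efficiency or degree) are selected per session, the set of nodes
connected to at least one of them is formed from the adjacency (a top
node joins the result only if adjacent to another top node; a flag
forces the whole top set in), session-overlapped, thresholded within
subject, and finally thresholded across subjects at 50% — a majority
of participants must show a connection for it to appear in the group
map. The whole-brain default (20%) and the ROI default (15%) are
separate parameters because the two analyses conventionally use
different cuts; both are configurable.

# ROI statistics and the repeated-measures ANOVA

ROI masks are spheres in mm space: a voxel belongs to the mask iff its
center lies within the radius (default 10 mm) of any listed center,
and bilateral ROIs are analysed as the union of their spheres. The ROI
metric value is the arithmetic mean over in-mask gray nodes.

State effects are tested with a fully within-subjects 2 (condition) ×
S (session) ANOVA computed by direct cell-means sums-of-squares
decomposition: subject, condition, session, condition × session, and
their subject-interaction error terms. Each effect is tested against
its own subject-interaction term, so with n subjects the condition
effect has df (1, n − 1). Effect size is partial eta squared,
SS_effect/(SS_effect + SS_error). No sphericity correction is applied
by default (the condition factor has df 1; the session factor is
reported uncorrected), and no multiple-comparison correction is made
across metrics. Degenerate tables are flagged rather than silently
propagated: zero error SS with positive effect SS reports F = Inf and
the boundary p = 0 with a warning; zero effect and error SS reports
NaN. The implementation is validated against `stats::aov` with
`Error(subject/(condition*session))` strata and against a brute-force
loop oracle, and its null type-I rate for the condition effect is
calibrated by simulation.

# The synthetic study generator

No scanner data ship with the package; the generator produces a
complete study — by default 5 subjects × (5 rest + 5 task) alternating
sessions of 120 volumes at TR = 2 s — on a desk-scale 14 × 14 × 10
grid of 4 × 4 × 5 mm voxels. Tissue classes are concentric
superellipsoidal shells (white core, thick gray shell of 1280 voxels,
thin CSF rim); the layout is arbitrary but fixed and documented.
Alternation starts with rest by default (`first_condition` flags the
alternative, since either ordering is plausible).

Each voxel's series is a sum of

* AR(1) noise (lag-1 coefficient 0.3, unit marginal variance),
* low-frequency scanner drift built directly from DFT bins below
  0.009 Hz (so its power is sub-band by construction), amplitude 2
  noise-SD units with per-voxel jitter,
* a shared physiological confound (loading ≈ 0.5) plus a
  tissue-specific confound per tissue class (loading ≈ 0.3) and
  motion-coupled signal from 6 random-walk motion parameters —
  the tissue-specific components matter: with only a single shared
  confound, the filtered global/white/CSF regressors are collinear up
  to the planted signal, and nuisance regression would remove the
  very correlations under study, which does not happen with realistic
  tissue-specific physiology,
* condition-dependent latent signals: band-limited unit-variance
  latent series (sums of in-band sinusoids) added to hub voxels with
  loading sqrt(c/(1−c)), so two voxels sharing a latent correlate at
  level c before filtering.

The planted structure encodes the state asymmetry the analysis is
meant to detect. The rest-dominant hub is a compact posterior-medial
block (three 8 mm spheres, 58 gray voxels, within-hub correlation 0.70
at rest vs 0.10 at task). Eight additional small modules (~10 voxels
each, radius 6 mm) each carry an *independent* latent at rest
(correlation 0.60, nearly off at task), emulating the many distinct
networks coherent during rest. The task-dominant hub is a bilateral
frontal-lateral pair (two 7 mm spheres, 32 voxels, correlation 0.60 at
task vs 0.10 at rest) coupled to a distal parietal region (18 voxels,
shared-variance 0.35 at task) — a working-memory-like fronto-parietal
circuit. Because the N = K^S rule fixes the edge budget, a single
large coherent block would monopolise edges and depress background
local efficiency; distributing the rest-state coherence over several
small modules is what produces the expected pattern — higher
whole-brain local efficiency at rest, higher rest-hub degree at rest,
higher task-hub degree during task — without degenerate networks.

Determinism is strict: identical configuration and seed give
bit-identical arrays, and the pipeline's summary tables are
byte-identical across reruns.

**What the generator does not emulate.** There is no hemodynamic
response convolution, no task-block structure within a session, no
spatial autocorrelation of noise (the acquisition was analysed
unsmoothed precisely to avoid local false correlations), no scanner
artifacts beyond drift/AR(1)/confounds, and no behavioral responses.
Passing end-to-end tests therefore demonstrates that the pipeline
recovers planted covariance structure through filtering, regression,
thresholding and graph summarisation — not that it would be robust to
every artifact of real acquisitions.

# Problem sizes and runtime choices

The default grid gives ≈1300 gray nodes, comparable in network terms
(K ≈ 10.9 at S = 3) to full-resolution studies while keeping a full
5-subject study to well under a minute. The test suite exercises
metric oracles on 100 random graphs of up to 60 nodes, density
thresholds up to N = 3375 (computed blockwise), ANOVA calibration on
2000 simulated tables, and end-to-end recovery on 10 seeded studies;
the acceptance script reruns the full pipeline on 10 seeds. Stage
caching was considered and rejected: at these sizes a rerun is cheaper
than cache bookkeeping, and determinism makes reruns exact.

# Interfaces

Volumes are NIfTI-1 (RNifti); motion parameters are 6-column
whitespace-delimited text; networks persist as edge-list TSV plus a
JSON metadata sidecar (N, S, r_threshold, K, edge count); metric and
consistency volumes persist as NIfTI with TSV summaries; the pipeline
writes a provenance manifest (config, seed, package version, and
per-session r_threshold and K). The package is R-native: the exported
stage functions (`generate_study()`, `preprocess_session()`,
`build_network()`, the metric and consistency functions,
`rm_anova_2xS()`) and the orchestrators `run_study()` /
`validate_inputs()` are the command surface, scriptable directly with
`Rscript`.

# Known limitations

* Whole-network means are taken over all gray nodes, including
  isolated ones (a flag for connected-node means is a possible
  extension); this matches the no-component-extraction convention.
* The blockwise correlation path still holds all upper-triangle values
  once (≈46 MB at N = 3375); truly large grids would need an external
  sort or a two-pass histogram quantile.
* The ANOVA assumes a complete balanced within-subject crossing and
  refuses anything else; dropped sessions must be handled upstream.
* Sphericity of the session factor is not corrected by default.
* ROI voxel counts depend on the grid and affine supplied; published
  counts from other software on other grids are not reproducible
  targets.
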