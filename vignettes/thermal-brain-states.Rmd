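---
title: "Static and dynamic functional connectivity of thermal perception: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional connectivity of thermal perception: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofc)
```

## The problem

Functional ultrasound (fUS) imaging records cerebral-blood-volume (CBV)
signals from awake, head-fixed mice while the floor temperature under their
paws is held constant (15, 25 or 35 °C) or ramped between those values.
After atlas-based segmentation, each imaging session reduces to ten ROI
time series — bilateral hindlimb somatosensory (S1HL), primary and
secondary motor (M1, M2), cingulate (Cg) and hypothalamic (HyTh) regions —
sampled at a few Hz. `thermofc` implements the full analysis that turns
these ROI series into (i) edge-wise *static* functional-connectivity
contrasts between thermal conditions and (ii) *dynamic* brain states
discovered by clustering per-frame cofluctuation patterns, together with a
synthetic cohort generator that provides ground truth for every stage.

## Signal conditioning

Awake imaging is contaminated by motion (grooming, licking, postural
shifts). The cleaning chain, in order:

1. **Artifact detection.** A frame is discarded when the robust z-score
   (median/MAD) of the tissue-motion reference exceeds 3, or the robust
   z-score of the mean absolute ROI deviation exceeds 3. Robust scores make
   the rule scale-free; both thresholds are configurable
   (`scrub_config()`). A threshold rule necessarily has a false-positive
   tail — about 1–2 % of clean frames at the defaults — which the
   synthetic benchmark quantifies.
2. **Epoch extraction.** Only maximal runs of at least 50 consecutive clean
   frames are kept, concatenated in temporal order; an acquisition with no
   such run is *discarded* with an explicit status. Epochs are stored
   0-based and half-open.
3. **Low-pass filtering** of the concatenated series at 0.1 Hz: 4th-order
   Butterworth applied forward–backward (zero phase, so no group delay
   distorts correlations). `signal::filtfilt` carries no initial-condition
   handling, so the package removes an endpoint-anchored baseline and pads
   by odd reflection before filtering; a constant passes through exactly
   and the startup transient stays outside the data. Filtering after
   concatenation follows the original processing order; `filter_per_epoch
   = TRUE` offers the seam-free alternative.
4. **Cubic detrending** per ROI (orthogonal-polynomial least squares).
5. **Optional moving-average smoothing** (off by default; the original
   description names a smoothing step without specifying it).
6. **Normalization**: per-ROI z-scoring.
7. **Global-component removal**: subtraction of the leading singular
   triplet of the row-centered ROI × time matrix. Note an important scale
   caveat: on pixel-level data the leading component is a genuine global
   (vascular/arousal) signal, but on a 10-ROI matrix the leading singular
   vector often *is* the dominant network mode, so this step also removes
   real network structure. The step is kept (configurable) because it is
   part of the reference chain; its consequences are measured below.

## Static functional connectivity

For every retained acquisition the 10 × 10 Pearson matrix is computed over
the cleaned, concatenated frames; its 45 upper-triangle values are Fisher
z-transformed (`atanh`, input clipped at ±(1 − 1e−7)). Each edge is then
contrasted between two thermal conditions with a linear mixed model

z ~ condition + (1 | animal)

fitted by REML, because animals contribute repeated, unbalanced sessions.
The condition p-value uses the Satterthwaite t approximation (lmerTest);
a normal-approximation Wald test is available as an option, but at the
cohort sizes in play (10–30 observations) it is anti-conservative, so the
t-based test is the default. When the animal variance component collapses
the fit falls back to ordinary least squares, flagged in the output.
Residual normality (Shapiro–Wilk) is reported but never used for gating.
The 45 raw p-values of one contrast form a single Benjamini–Hochberg family
at FDR 0.05 (families are not pooled across contrasts). Under a null
simulation with a real animal random effect the type-I error of this
machinery is 0.046 at nominal 0.05 (1000 replicates; recomputed in the
test suite).

## Dynamic functional connectivity

Writing $z_i(t)$ for the per-acquisition z-scored ROI signals (sample-SD
normalization), the per-frame cofluctuation matrix is $C_{ij}(t) = z_i(t)
z_j(t)$. Its upper triangle including the diagonal (55 values for ten
ROIs) is one observation; the identity
$\sum_t C_{ij}(t) / (T-1) = r_{ij}$ ties the dynamic decomposition exactly
to the static Pearson matrix, and the package asserts it to 1e−10.
Z-scoring is per acquisition, before cohort concatenation, so the identity
holds within every acquisition and session-level gain differences drop out.

Outlier frames are removed before clustering: each frame's mean L1 distance
to all other frames is z-scored (mean/SD over frames) and frames above 3
are discarded. The mean distances are computed by per-coordinate sorted
prefix sums, $O(55\,T\log T)$, never materializing the $T \times T$
distance matrix; the test suite checks exact agreement with the brute-force
$O(T^2)$ computation.

Brain states are the clusters of an L1 k-means (k-medians): manhattan
assignment alternating with coordinate-wise median updates, 500 random
initializations by default (each initialized at K distinct frames; restart
RNG streams derive deterministically from the master seed), keeping the
run with the lowest total within-cluster L1 distance. Empty clusters are
re-seeded at the frame farthest from its assigned centroid. Convergence is
declared when assignments stop changing, capped at `max_iter`. States are
relabeled by descending occurrence (ties by centroid norm), so state 1 is
always the most frequent. The core iteration is compiled (Rcpp).

The number of clusters is examined with the Duda–Hart split criterion: for
each K, every cluster's two-way split ratio Je(2)/Je(1) (within-cluster
squared error after/before a 2-means split) is compared with
$1 - 2/(\pi d) - z_\alpha \sqrt{2(1 - 8/(\pi^2 d))/(n d)}$; the selected K
is the smallest whose split count is zero and stays zero. Clusters smaller
than $2d$ frames are exempted to avoid degenerate statistics; a seeded
subsample (`max_frames`) keeps the scan affordable on long recordings.

Occurrence rates — the fraction of an acquisition's retained frames in
each state — are compared across conditions per state with the same mixed
model structure (multi-level condition fixed effect, Satterthwaite omnibus
F); pairwise condition contrasts are fitted only when the omnibus effect is
significant at 0.05 and are BH-adjusted within the state. An
animal × state composition table with a descriptive chi-square guards
against states driven by a single animal.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, emulating the
statistical structure the analysis assumes:

- **Seven covariance templates** (correlation-scaled, verified positive
  definite): one weakly connected state; three states with a strong
  somatomotor–cingulate block anticorrelated with the hypothalamus; one
  state with the cingulate decoupled from everything; two intermediate
  states.
- **Sticky Markov switching** (stay probability 0.95 per frame) whose
  stationary distribution equals the animal- and condition-adjusted
  occupancy; the neutral condition is dominated by the weak state, cold
  fast-down ramps favor the dichotomy states, sustained cold the
  cingulate-decoupled state.
- **Per-animal random effects** on occupancy logits (SD 0.3), drawn once
  per animal and shared across sessions — the structure the downstream
  random-intercept models assume.
- **Band-limiting** by an AR(1) recursion (coefficient 0.9, unit marginal
  variance) rather than an explicit filter: cheaper, and the low-pass is
  tested independently.
- **Slow drift** (random cubic, SD 0.5 in z-units), a **shared global
  component** (SD 0.5), and **multiplicative motion bursts** (Poisson rate
  3 per 1000 frames, 1–10 consecutive frames, gain 10) mirrored as spikes
  in the motion reference. The baseline motion-energy trace is a narrow
  Gaussian around a positive level, reflecting that tissue-motion energy
  averages many pixels; no published artifact statistics exist for awake
  fUS, so these are stated, configurable assumptions.
- The default sampling rate is 2.5 Hz (the reference chain fixes only the
  0.1 Hz cutoff, not the frame period; `fs` stays configurable) and 3000
  frames per acquisition (20 min at 2.5 Hz).

What the generator does *not* emulate: hemodynamic response convolution,
pixel-level speckle, spatially varying artifact footprints, non-Markovian
dwell times. Passing tests therefore demonstrate correctness of the
analysis machinery under the stated model, not fidelity to every property
of real fUS data.

## What desk-scale synthetic cohorts can and cannot recover

Running the full chain on default synthetic cohorts exposes two structural
limits that are properties of the method, not implementation defects; both
are quantified in the acceptance suite and documented here because they
shape what a user should expect:

- **Per-frame cofluctuation clustering cannot reconstruct the generating
  covariance templates with high fidelity.** A single frame's
  cofluctuation vector is a product of Gaussians: within-state coordinate
  SD ≥ 1 against between-state centroid differences ≤ ~1.4, with strong
  excess kurtosis. Even *oracle* centroids computed from ground-truth
  labels correlate only 0.5–1.0 with their templates after the default
  chain (the ROI-level global removal is the largest single distorter —
  see the caveat above; without it oracle correlations are 0.85–0.99),
  and k-means fragments the dominant weak state, diluting per-acquisition
  occupancy contrasts. Planted occupancy effects that the mixed-model
  layer recovers perfectly from ground-truth labels are therefore mostly
  invisible after clustering at desk scale.
- **The Duda–Hart criterion never settles on product data.** The split
  test is a Gaussianity test: heavy-tailed cofluctuation clouds always
  admit a 2-means split that beats the Gaussian-derived critical ratio, so
  the split count stays positive at every K. The criterion behaves
  correctly on Gaussian references (single blob: no split; separated
  blobs: the true K), which the unit tests assert.

## Numerical and design choices

- Vectorization of symmetric matrices is row-major upper triangle, fixed
  package-wide; frames are 0-based with half-open epochs.
- Symmetry tolerance 1e−10; PSD tolerance 1e−8 for correlation matrices.
- Outlier z-scores use the plain mean/SD of mean distances (not robust z),
  in a single pass.
- The BH family is the testable edges of one contrast (≤ 45); `reject` is
  `adjusted < q`.
- Mixed-model "untestable" designs (fewer than 2 animals or 3 observations
  per condition, or a missing condition) are excluded from the BH family
  with an explicit status.
- Per-restart k-means seeds derive from the master seed; identical
  configuration + seed reproduces labels, centroids and every table
  bit-for-bit.
- Sessions enter the mixed models as repeated measures (not averaged per
  animal); the random intercept absorbs the animal level.

## Problem sizes used by the shipped analyses

The analysis scripts and the acceptance recomputation run cohorts of six
animals with 1–2 sessions per condition and 600–3000 frames per
acquisition, with 4–50 k-means restarts, chosen so a complete run stays in
the minutes range on a single core; the statistical designs for the
calibration checks (e.g. 1500-frame acquisitions, two sessions per
condition for the planted-effect recovery) were sized by a power analysis
of the ground-truth layer so that the mixed-model stage has ≥ 95% power
before clustering enters. The k-means default remains 500 restarts for
production use.

## Known limitations

- The ROI-level global removal caveat above: with only ten ROIs the
  "global" component is partly network signal. Consider `remove_global =
  FALSE` when the upstream data were already globally filtered.
- The artifact thresholding statistic is an assumption (the reference
  description calls only for investigated thresholds); its robust-z form
  breaks down if a majority of frames are artifactual.
- Duda–Hart K selection is informative only for near-Gaussian cluster
  residuals; on raw cofluctuation frames prefer a fixed K with stability
  checks.
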