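---
title: "From hand joint angles to individuality: the methods behind handovr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hand joint angles to individuality: the methods behind handovr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

When two people hand an object across a table, the short motion of the
giving and receiving hand is shaped by several layers of influence at once:
who is moving (a stable personal signature), what the situation demands
(object size, weight, whether the transfer is direct or via a surface, which
side gives), and, possibly, stable traits of the person (age, body size,
personality). `handovr` implements a pipeline that quantifies how much a
single short joint-angle recording reveals about each of these layers, and a
synthetic trajectory generator that lets every stage be exercised, tested
and calibrated without access to motion-capture recordings.

The working hypothesis the generator encodes — and the analysis is designed
to detect — is a hierarchy of effect sizes:

> identity effect ≫ condition effect ≫ trait effect.

## Data model

A trial is one hand-over under one of the 32 experimental conditions: the
full factorial of five binary factors (platform present/absent, beaker
big/small, direct/indirect hand-over, full/empty, giver left/right), with
three replicates per condition in the default design (96 trials per pair of
participants). Each trial yields two trajectories, one per hand: a T × 20
matrix of joint angles in radians, 4 rotational degrees of freedom per digit
for 5 digits. Global hand translation and rotation are deliberately absent
from the representation: they vary with seating and posture even for the
same person under the same condition, so only intrinsic hand shape over time
is analysed.

## The synthetic generator

`generate_trajectory()` composes, per channel and time step:

1. a fixed smooth reach–grasp–release template;
2. a participant signature (channel offsets plus a random-centred bell,
   scale `sigma_identity`, default 0.6 rad), drawn once per participant and
   frozen across all of that participant's trials;
3. additive condition components (smooth low-frequency shapes whose sign
   flips with the factor level, scale `sigma_condition`, default 0.25 rad)
   for four of the five factors — the fifth, the side of the giver, acts by
   time-inverting the whole profile, because swapping giver and receiver
   inverts the temporal structure of the movement;
4. trait components linear in the z-scored profile fields (scale
   `sigma_trait`, default 0.08 rad), standardized against fixed reference
   moments so a single profile can be generated in isolation;
5. i.i.d. Gaussian noise (`sigma_noise`, default 0.05 rad);

and finally evaluates the sum on a smoothly warped time grid (`warp_jitter`,
default 0.1 of the duration) with the number of samples drawn from 80–120
per trial, so that temporal alignment is never trivial. The defaults keep
the intended ordering `sigma_identity > sigma_condition > sigma_trait` with
roughly a factor 2–3 between layers; they were chosen once, from the
qualitative description of the phenomenon, and the test suite verifies that
the between/within DTW distance ratios actually realize the ordering.

Tracking failures (the hand model of the original capture system could
confuse the two right hands) are modelled as a per-trial Bernoulli flag —
the study discarded such trials rather than repairing them — and
`filter_valid()` excludes every trial of any participant whose failure
fraction exceeds 0.5. Because a hand-swap corrupts both hands, a failing
participant drags their partner's trials out with them, which is exactly how
two of the original ten participants dropped out.

What the generator does **not** emulate: joint-limit constraints,
biomechanical coupling between digits, autocorrelated sensor noise, marker
occlusions, or any kinematic realism beyond smoothness. Passing tests
therefore demonstrate that the *analysis machinery* behaves as specified
under the assumed statistical structure — not that real hands behave this
way.

## Distances: multivariate DTW

`dtw_distance()` is the classic dynamic program over monotone warping paths
with unit steps (diagonal, horizontal, vertical) and endpoint constraints;
the local cost is the unsquared Euclidean norm of the 20-dimensional angle
difference, which keeps the result in radians. No band or slope constraint
is applied by default (a Sakoe–Chiba band is available for speed), the
accumulated cost is not normalized by path length by default (with roughly
equal trajectory lengths normalization acts monotonically, and the
downstream nonmetric embedding consumes ranks only), and channels enter in
raw radians (a standardization switch exists but all channels share units).
The implementation is compiled; the test suite pins it against exhaustive
enumeration of all admissible warping paths on short series.

## Embedding: nonmetric MDS under stress-1

`nmds_embed()` minimizes Kruskal's normalized stress-1,

$$\sigma_1 = \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}{\sum_{i<j} d_{ij}^2}},$$

alternating isotonic (pool-adjacent-violators) regression of the
configuration distances on the dissimilarity ranks with a SMACOF-style
Guttman update toward the disparities. Numerical choices:

* **start**: classical (Torgerson) scaling, with random starts for
  additional replicates;
* **ties** in the dissimilarities follow Kruskal's primary approach (tied
  values unconstrained against each other, implemented by secondary-sorting
  distances within tie blocks);
* **termination**: stress change below `tol_fun` (1e-4), maximum coordinate
  change below `tol_x` (1e-4), or 200 iterations — whichever comes first,
  with one replicate by default;
* an iteration that would increase stress-1 is rejected and iteration
  stops, so the reported stress trace is non-increasing by construction;
* an all-zero dissimilarity matrix is degenerate for the normalization and
  handled by jittering the start; an all-zero configuration raises an
  explicit error in `stress1()`.

Embeddings are computed at dimensions 1, 2, 3 and 20: 3 for visual
inspection of the cluster structure, 1/2/3/20 as "trajectory factors" for
the mutual-information matrix, and 20 as input to the classifiers.

## Supervised recognition: LVQ under two cross-validation regimes

`lvq_train()` is LVQ1: prototypes attracted to same-label winners, repelled
otherwise, with a linearly decaying learning rate; prediction is
nearest-prototype with deterministic low-index tie-breaking. Two fold
schemes matter scientifically: *trialwise* folds (the network has seen other
trials of the test person — tests whether the factor is encoded at all) and
*participantwise* folds (one fold per person — tests generalization to
unseen individuals). Per fold the error fraction and the chi-square
cross-tabulation p-value ("asymptotic significance", no continuity
correction, degenerate single-row/column tables reported as p = 1) are
recorded and averaged.

Two deliberate choices deviate from the simplest defaults, both visible in
`pipeline_config()`:

* **classification dimension 20, not 3.** Diagnostics on synthetic data
  show the DTW distances carry all factors essentially perfectly (1-NN
  error ≈ 0), but a 3-dimensional projection collapses onto the dominant
  identity/role clusters and destroys the condition information (1-NN
  errors of 0.3–0.5). The full-rank 20-dimensional projection keeps it.
* **8 prototypes per class, sampled initialization.** A condition-factor
  level's point cloud is a union of participant-and-role clusters; a single
  prototype at the class mean cannot represent such a multimodal class, so
  the pipeline initializes several prototypes at random class samples. The
  bare operation keeps the single-prototype, class-mean default.

## Unsupervised coding: the 2-per-axis, 8-axis map

The self-organizing map has two units along each of eight lattice axes —
256 units in total, each addressed by an 8-tuple over {0,1} (row, column,
plane, cube, tesseract, penteract, hexeract, hepteract). A hexagonal layout
is not realizable with two units per axis in eight dimensions, so the
lattice is the {0,1}^8 hypercube and neighbourhoods are Gaussian in Hamming
distance. Training is the classic online rule with linearly decaying
learning rate and radius; coding takes the best-matching unit's coordinate
tuple, with lexicographic tie-breaking. Under cross-validation each fold is
coded by a map trained on its complement, so no trajectory is coded by a
map that saw it.

## Statistics

**Mutual information** uses a two-pass histogram protocol: descriptors
(cell layouts) are fixed from the data first — one cell per category for
discrete inputs, `ceiling(1 + log2 n)` equal-width cells for continuous
ones — then the plug-in estimate in bits is corrected by the first-order
Miller–Madow bias term $(R_x - 1)(R_y - 1) / (2N\ln 2)$. The MI matrix
treats every projection component as its own factor and is drawn with a
percentile colour scale, because the raw values span orders of magnitude.

**MANOVA** over the 8 binary BMU coordinates forms hypothesis and error
cross-products with Type II sums of squares (types coincide on the balanced
synthetic designs) and reports Pillai's trace, Wilks' Λ, the
Hotelling–Lawley trace and Roy's largest root with their standard
approximate F tests. Numerically the statistics are computed from the
bounded eigenvalues θ of $(E+H)^{-1}H$ rather than $E^{-1}H$: on synthetic
data the codes can be a near-deterministic function of participant and
condition, which makes $E$ singular in perfectly explained directions. In
the θ-parameterization this limit is well-defined (θ → 1, i.e. an infinite
root and p → 0 for Wilks/Hotelling/Roy), and the two parameterizations are
algebraically identical whenever $E$ is regular — the tests pin the
implementation against `summary.manova` to 1e-8. Null directions of $E+H$
carry nothing about the term (both $E$ and $H$ vanish there) and are
projected out; responses with no variation at all raise an error naming the
columns. Backward model reduction drops, per round, the factor with the
worst (largest, over folds) Wilks p at or above α = 0.05, with ties broken
toward the earlier column, until every survivor is significant in every
fold.

The per-fold MANOVA scheme mirrors the cross-validated coding: for each
participantwise fold the map is trained on the complement and *all* trials
are coded by it. A fold-only MANOVA could not carry a participant term
(each fold holds one participant), so the model runs on the full coded set
while the held-out participant's codes still come from a map that never saw
them.

## Problem sizes and reproducibility

The package's own verification runs at two scales, chosen to keep the whole
suite comfortably interactive: a battery of ten independently seeded
datasets at 2 pairs × 32 trials (replicates = 1, 60–80 samples per
trajectory) for the hierarchy-recovery properties, and one full-study-scale run
at 4 pairs × 96 trials (768 trajectories, 80–120 samples) through the full
pipeline. A single global seed fans out to every stage through a
counter-based substream scheme, and re-running any configuration reproduces
every numeric output bit-for-bit; the run manifest records the seed and a
configuration hash.

## Known limitations

* The generator's additive, phenomenological templates make recognition
  *easier* than real motion data would; absolute error rates are not
  comparable to values obtained on recordings, only the ordering of effects
  is meaningful.
* LVQ and SOM results depend on their stochastic training; the pipeline
  fixes seeds, but different seeds give (slightly) different tables, as is
  expected of these networks.
* The MI estimator's bias correction is first-order; diagonal dominance of
  the MI matrix is guaranteed only for the uncorrected plug-in estimate.
* Roy's largest root uses the standard upper-bound F approximation and is
  anti-conservative, as usual.
* The repeated-measures variant of the unsupervised analysis is out of
  scope: only its non-result is known, with no model specification to
  implement.
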