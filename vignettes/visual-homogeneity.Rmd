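---
title: "Visual homogeneity as a distance-to-center decision variable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual homogeneity as a distance-to-center decision variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vishom)
```

## The model

Several visual tasks that look dissimilar on the surface — deciding whether
an oddball target is present in a search array, or whether an object is
symmetric — share a common structure: the observer must judge how
*homogeneous* the display is. This package implements a quantitative account
of that judgement built from three ingredients.

**1. A perceptual space from search times.** In an oddball search task the
time to find a target among identical distractors falls as the two items
become more discriminable, and the reciprocal of the mean correct search
time, $1/\mathrm{RT}$ (units s$^{-1}$), behaves as a perceptual
dissimilarity. Measuring all pairwise searches over a stimulus set yields a
symmetric dissimilarity matrix, which multidimensional scaling (MDS) embeds
into $k$ dimensions so that inter-point distances reproduce the observed
dissimilarities. Each embedding dimension can be read as the response of one
artificial neuron, so the row of coordinates for an object is its population
response vector.

**2. Multiple-object averaging.** The response to an array containing
several items is modeled as the average of the single-item response vectors.
Two consequences matter here: the response to an array of identical items
(a target-absent display) *equals* the single-item response, and the
response to a target-plus-distractor array is a convex combination of the
two item responses — it collapses toward other mixed displays. A weighted
variant, $w\,r_\mathrm{target} + (1-w)\,r_\mathrm{distractor}$ with $w$
normalized into $[0,1]$, makes the averaging assumption testable:
`weight_sweep()` refits the model over a grid of $w$ and reports where the
fit peaks.

**3. Visual homogeneity (VH).** VH of a display is the Euclidean distance of
its (averaged) response vector from a center point $c$ in the embedding.
Because mixed (target-present) arrays collapse toward each other while
homogeneous (target-absent) arrays stay spread out, VH separates the two
kinds of display, and the theory takes VH to be the decision variable:
responses are slowest where VH is closest to the decision boundary. This
predicts a *positive* VH–RT correlation for the low-VH group
(target-present, or asymmetric objects) and a *negative* one for the
high-VH group (target-absent, or symmetric objects), and — when the two
groups straddle the boundary symmetrically — a pooled correlation near
zero. The center is not free to be anything: `fit_center()` chooses $c$ to
maximize

$$ J(c) \;=\; r_A(c) - r_B(c), $$

the difference between the group-wise Pearson correlations of VH with mean
RT. $J$ is bounded by 2, attained exactly when the within-group links are
perfectly linear with the predicted signs.

## Fitting choices

*Optimizer.* $J$ is piecewise-smooth (distances are non-differentiable where
the center coincides with a response), so the fit uses derivative-free
Nelder–Mead (golden-section in one dimension) from the response centroid
plus random restarts (default 20) drawn uniformly inside box bounds. The
bounds default to the response bounding box expanded by 50% per dimension;
the objective is evaluated with the candidate clamped into the box, which
implements the constraint without penalty terms. All restart optima are
returned so the stability of the solution is auditable; among numerically
tied optima the smallest-norm center is reported, and any center component
orthogonal to the affine span of the responses (a direction the objective
cannot see) is projected out before reporting.

*Correlation type.* Pearson throughout, since the model asserts a linear
within-group link; Spearman is available via `method = "spearman"` for
robustness checks.

*Cross-validation.* `loocv_fit()` removes every display involving one
object, refits the center (warm-started from the full-data center plus
random restarts), and predicts VH for the held-out displays; a display
involving two objects is predicted in both folds and the predictions are
averaged. `dimension_sweep()` runs this for each candidate $k$ and applies
a plateau rule: the selected $k$ is the smallest whose
$|r_A| + |r_B|$ lies within a tolerance (default 0.05) of the sweep
maximum. The correlation-vs-noise-ceiling comparison is reported only as a
diagnostic (`fit_r` against `split_half_consistency()`), not used for
selection.

*Rigid-motion invariance.* MDS fixes geometry only up to rotation,
reflection and translation; every quantity downstream of the embedding (VH,
$J$, all correlations) is invariant to those transforms, and the test suite
asserts this.

## The synthetic-data generator

All inputs can be simulated with known ground truth, which is how the
package validates itself.

* **Latent space.** Objects are drawn i.i.d. from an isotropic Gaussian
  with scale `spread` per dimension. Two design constraints keep the
  simulated psychophysics physical: a minimum pairwise distance
  (`min_dist`, default 0.4 s$^{-1}$) and a maximum norm (`max_radius`,
  default 1.4 s$^{-1}$), so that noiseless search RTs $1/d$ stay inside the
  0.3–3 s trial-filter window — a stimulus set a careful experimenter would
  have chosen, since searches outside that window are unmeasurable. The
  defaults (32 objects in 5 dimensions for the search study, 64 in 3 for
  the symmetry study, 16 participants, 2 trials per pair per participant)
  mirror the scale of the behavioural experiments the analysis is designed
  for.
* **Search trials.** Trial RT is $1/d + \varepsilon$,
  $\varepsilon \sim N(0, 0.1\,\mathrm{s})$, clamped below at 0.05 s. The
  clamp keeps RTs physical; no trial-level RT distribution is implied by
  the analysis itself, so the Gaussian is a configurable stand-in (a
  lognormal would serve as well — the downstream pipeline only consumes
  pair means).
* **Decision trials.** Each display's RT is
  $t_{\max} - \beta\,|VH - b| + \varepsilon$ clamped at the floor:
  slowest at the boundary $b$, faster with distance from it. Defaults
  $t_{\max} = 1.8$ s, $\beta = 0.5$ s per unit VH place RTs in a realistic
  0.8–1.8 s band. The boundary defaults to the median display VH, so the
  two response groups are exactly balanced — mirroring the scanner task's
  32-present/32-absent runs, and a requirement for the group-z-scored
  VH/RT dissociation to be exact — and group labels follow the side of
  the boundary, which makes the noiseless within-group links exactly
  linear (correlations $\pm 1$, objective 2), the property the recovery
  tests lean on. Trial noise is specified as a fraction of the noiseless RT
  range (default 10%); with several simulated participants the
  per-display mean is correspondingly less noisy. Accuracy is Bernoulli
  (default 98%) and incorrect trials are flagged, not dropped, so the
  filtering stage has real work to do.
* **Voxel volumes.** `gen_voxel_data()` plants a VH-coding region
  (activation linear in VH), an RT-coding region, and i.i.d. Gaussian noise
  elsewhere, on an arbitrary masked grid, optionally per subject. Random
  streams are split per operation, so generating more behavioural trials
  never perturbs the voxel noise.

What the generator does *not* emulate: spatial item layouts and set-size
effects, eye movements, RT autocorrelation across trials, spatially
correlated fMRI noise, hemodynamics, or between-subject variability in the
perceptual space itself. Passing recovery tests therefore demonstrates that
the estimation machinery is correct and well-conditioned at realistic noise
levels, not that real cortex contains a VH region.

## Searchlight procedures

Two voxel-wise maps are computed on masked 3-D grids, mirroring the
behavioural model's two levels:

* **Mean-activation map** (`vh_correlation_map()`, `rt_correlation_map()`):
  for each in-mask voxel, the mean activation over its mask-clipped
  3×3×3 neighborhood per condition is z-scored *within each decision
  group* (this removes overall activation differences between groups — the
  same transform is applied to the predictor), then correlated with VH or
  RT across conditions. With equal group sizes, group-wise z-scoring makes
  a VH-coding voxel approximately orthogonal to the RT predictor and vice
  versa, which is the dissociation the planted-region tests check.
* **Neural-dissimilarity map** (`rdm_correlation_map()`): each voxel's
  response vector to an object is its neighborhood activation pattern (up
  to 27-dimensional, fewer at mask edges; the dimensionality is recorded
  per voxel); all pairwise Euclidean distances between object patterns are
  correlated with the perceptual dissimilarities.

Clusters are extracted with 26-connectivity above a user-chosen threshold
(`define_region()`); the threshold and minimum cluster size are explicit
parameters because no principled default exists at synthetic scale. Region
summaries (`region_mean_correlation()`) bootstrap participants with
replacement (default 10,000 resamples) for a standard deviation and a
one-sided sign-violation p. Voxel coordinates are reported 1-based, the R
array convention.

## Numerical choices and degenerate inputs

* MDS: SMACOF majorization of raw metric stress, normalized as
  $\sqrt{\sum (d - \hat d)^2 / \sum d^2}$, tolerance $10^{-8}$ on the
  stress decrease, at most 500 iterations, classical scaling
  initialization plus perturbed restarts (default 10). Kruskal's
  nonmetric stress-1 is available as an option. A dissimilarity matrix
  with zero variance embeds exactly but has undefined `fit_r`, which is
  returned as `NA` with a note rather than an error.
* Zero RT or VH variance within a group makes the objective undefined;
  `vh_objective()` raises an error naming the group, while the optimizer
  treats such centers as maximally bad and moves away.
* A zero inter-object distance with zero search noise would produce an
  infinite RT; the generator refuses and tells the caller to perturb the
  embedding.
* Group-wise z-scoring with a zero-variance group returns `NaN` for that
  group with a warning; searchlight maps store `NaN` at degenerate voxels
  and count them.

## Problem sizes used in the test suite

The recovery simulations run at the generator's study conditions
(32 objects, 5 dimensions, decision noise 10% of the RT range): 200
simulated datasets for the sign-recovery and LOOCV-stability checks, 100
planted-volume simulations on a 20×20×20 grid with 64 conditions and
signal-to-noise 2 for the searchlight checks, and 20 random 2-D problems
against an exhaustive 101×101 grid-search oracle for the optimizer. The
weight-sweep recovery uses a 0.025-spaced grid and decision noise of 5% of
the RT range, a deliberately sharper condition chosen so the one-parameter
family is resolvable at the grid spacing. Monte-Carlo oracle bands in the
unit tests use 200–2000 resamples.

## Known limitations

* The center fit is a multi-start local search; on pathological geometries
  a 101×101 grid oracle is the arbiter (the suite includes one), and more
  restarts are the remedy.
* The LOOCV refit can be degenerate for very small object sets (fewer than
  three displays per group in a training fold); such folds are skipped with
  a warning rather than silently fitted.
* Dissimilarities are assumed complete: every object pair must retain at
  least one correct trial after filtering, or
  `dissimilarity_from_trials()` stops and lists the missing pairs.
* The decision model is a static distance-to-boundary account; no
  evidence-accumulation dynamics are modeled, and the resolution of
  overlapping VH ranges by closer scrutiny is out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- default_config("search_study")
cfg$seed <- 1
report <- run_search_study(cfg)
report$fit$objective      # opposite-sign correlation objective
report$loocv              # cross-validated group correlations
```
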