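---
title: "Componential kinematic encoding: models, synthetic worlds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Componential kinematic encoding: models, synthetic worlds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Object-directed actions can be described componentially: a closed set of
kinematic synergies -- stereotyped postures and movements of the fingers,
hand, wrist, and arm -- recombines to form the action associated with any
graspable object. If the brain encodes object-directed actions this way,
then a voxel's response to an object should be predictable as a weighted
sum of that voxel's responses to the object's constituent synergies,
with weights set by independent behavioural ratings of how relevant each
synergy is to the object.

`synkin` implements that analysis as a reusable pipeline: a leave-one-out
rating-weighted linear encoding model over per-object beta volumes,
voxelwise scoring of predictions ("univariate RSA"), searchlight RSA
against model similarity matrices, group inference with TFCE and
sign-flip permutation, dendrogram entanglement for behavioural similarity
spaces, behavioural-amplitude correlation maps, and ROI-level model
comparison. Because the analysis is validated on synthetic cohorts with
planted ground truth, every stage has a parameter-recovery test.

# The encoding model

For each subject and each held-out object $t$, the model runs two steps:

1. **Synergy maps.** For each synergy $s$, the objects (excluding $t$)
   with group loading strictly above 0.75 form the high set, those
   strictly below 0.25 the low set. The synergy's whole-brain map is the
   average over all (high, low) pairs of the pairwise volume
   differences, which algebraically equals `mean(high) - mean(low)`. If
   either set is empty, the map is *absent* -- a modelled outcome, logged
   per fold, contributing zero to predictions.
2. **Prediction.** The held-out object's activity at voxel $v$ is
   $\hat y_v = \sum_i s_{vi}\, k_i(t)$: the synergy maps weighted by
   $t$'s own group loadings, summed, with no renormalisation. A
   sum-to-one normalisation of the weights is available behind
   `normalize_weights = TRUE` for sensitivity analysis only.

Predictions are scored per voxel by the Pearson correlation across
objects between observed and predicted activity, Fisher z transformed
(with $r$ clamped to $\pm(1 - 10^{-7})$ so perfect correlations stay
finite). Zero-variance voxels are flagged invalid (`NA`), never zeroed,
and are dropped from group statistics; voxels valid in fewer than 80% of
subjects are excluded from group maps for stability.

Group inference follows the order r → Fisher z → smooth (6 mm FWHM,
masked Gaussian with edge renormalisation) → one-sample two-tailed t →
TFCE (H = 2, E = 0.5, 100 integration steps, 6-connectivity) → sign-flip
permutation correction using the maximum in-mask |TFCE| across both
tails. Sign flipping is the only valid exchangeability scheme for a
one-sample design. FDR cluster correction (clusters at two-tailed voxel
p < 0.001, cluster extents referred to a sign-flip extent null,
Benjamini–Hochberg across clusters) and a Monte-Carlo cluster-extent
threshold (95th percentile of the null maximum cluster size) are
provided for the amplitude-map and replication-style analyses.

# The synthetic world

`synth_config()` defaults state the emulated design: 54 synergies rated
by 87 raters over 33 high-centrality objects, 25 subjects, a 24×24×24
grid of 3 mm voxels with a spherical brain mask (~40% of the grid), and
disjoint planted regions taking 8% (kinematic), 8% (visual), and 6%
(centrality) of in-mask voxels; the rest is pure-noise null.

**Ratings.** Synergies and objects belong to latent action families --
by default, object *pairs* that share a manipulation pattern, the way a
corkscrew and a screwdriver share a twisting action. A rater marks a
synergy involved with probability 0.9 for objects of the synergy's own
family and 0.1 otherwise; 20% of cross-family synergy–family relations
are ambiguous, with involvement probability drawn from (0.3, 0.7).
Ambiguity is a property of the synergy–family relation, not of the
individual object, so family mates have identical expected loadings and
differ only by rater sampling noise. Forced high (own family) and low
(sampled out-family) cells are vote-resampled (capped at 1,000 attempts)
until the loading constraint (> 0.75 / < 0.25) holds, so every synergy
keeps non-empty high and low sets after any single object is held out.

Two properties of this design matter and were chosen deliberately:

* *Recoverability.* Because a held-out object's family mate is a
  faithful stand-in for it, the encoding model can predict unseen
  objects almost perfectly in the noiseless limit (planted-region mean
  r > 0.9). With fully unstructured ratings, synergy-to-synergy
  cross-talk in the contrast maps caps noiseless recovery near r = 0.5
  regardless of noise level -- no amount of data fixes it, because the
  imperfection is in the feature geometry, not the measurement.
* *Leave-one-out neutrality.* Any correlation-scored leave-one-out
  encoding model is slightly anticorrelated with pure noise: the
  held-out object's own volumes are excluded from its synergy maps, so
  within a training family the prediction varies against the held-out
  member. With larger families ("mean of the others") this artefact is
  of order −0.05 and, being consistent across subjects, would dominate
  group statistics in no-signal regions. With pair families the
  exclusion becomes a symmetric partner swap and the artefact shrinks by
  an order of magnitude. It does not vanish: the residual is visible to
  tests that compare regional means against standard errors of order
  0.001. The
  permutation-destruction test is therefore one-sided (misaligned
  ratings must show no *positive* prediction), and this artefact is the
  reason.

**Volumes.** Synergy spatial patterns are smoothed Gaussian random
fields inside the kinematic region, mean-centred per voxel across
synergies (so high-vs-low contrasts are informative without
hand-tuning), then scaled so the planted signal has unit average
across-object standard deviation at `effect_scale = 1`; `noise_sd` is
thus interpretable as a noise-to-signal ratio, and the default
`noise_sd = 1` is "moderate noise". The visual region is linear in the
supplied feature matrix (scaled the same way); the centrality region's
amplitude is `gain(v) * z(centrality)` with voxel gains uniform on
(0.5, 1.5). Centrality and familiarity are drawn uniform on the 1-5
rating scale and z-scored; familiarity is decorrelated from centrality
by construction (residualised, then rescaled) so the planted
dissociation is identifiable -- with only 33 objects, two independent
uniforms correlate at ±0.17 by chance, which would contaminate the
"familiarity shows nothing" contract for reasons unrelated to the
pipeline. Noise is Gaussian, independent across subjects and objects,
with spatial smoothness of 6 mm FWHM (preprocessed beta maps have
spatially correlated noise; white noise would also understate
between-subject variance of smoothed group maps). A per-subject ±10%
signal-scale jitter adds realistic between-subject variance.

**What the generator does not emulate.** No haemodynamics, GLM fitting,
run structure, motion, anatomy, or spatial normalisation; no
subject-specific functional topographies; noise is Gaussian and
homoscedastic. A green recovery test establishes that the pipeline's
statistics are correct and its inference calibrated under a known
generative model -- not that a comparable effect exists in real brains.

**Evaluation masks.** Because 6 mm smoothing genuinely spreads planted
signal into adjacent voxels, the ground truth includes `null_strict`:
null voxels outside a 4-voxel dilation of all signal regions.
False-positive assertions use `null_strict`; penumbral voxels are
excluded from both sides rather than counted as errors, since rejecting
them would penalise correct inference about smoothed truth.

# The kinematic state space

Object similarity is `1 - r` over loading columns (an RDM; entries in
[0, 2], diagonal 0), clustered with Ward's criterion applied directly to
the correlation-distance matrix (`hclust`, `ward.D2`). Ward formally
assumes squared Euclidean distances; applying it to correlation
distances follows the stated analysis procedure, and the caveat is noted
here once.

Entanglement between two trees is
$\sum_i |x_i - y_i|^L / \sum_i |x_i - \tilde x_i|^L$, where $x, y$ are a
leaf's ranks in the two displayed orders, $\tilde x$ is the reversed
order (the worst case), and $L = 1.5$ by default (the common convention;
configurable). `entanglement()` scores the leaf orders *as given*;
`untangle_stepwise()` -- a deterministic greedy hill-climb over single
internal-node rotations of either tree -- is a separate, explicit step.
Keeping them separate preserves the endpoint semantics (identical trees
give exactly 0; reversed ladders give exactly 1) that would be destroyed
if untangling were silently applied first. The permutation test shuffles
the leaf labels of one tree and is left-tailed,
$p = (1 + \#\{e_{null} \le e_{obs}\})/(n_{perm} + 1)$, since small
entanglement means alignment.

The high-centrality subset is the objects strictly above the median
rating; ties at the median are excluded, which reproduces a 33-of-66
split whenever the values are distinct and makes the rule reproducible.

# Searchlight and model comparison

The searchlight uses Euclidean spheres in voxel units (default radius 3,
centre included, at least 10 in-mask voxels), local neural RSMs by
Pearson correlation over object patterns, and Spearman rank correlation
between the strictly-lower-triangle vectors of neural and model RSMs
(Pearson by flag). Radius and comparison statistic are field-standard
defaults; neither is dictated by the emulated study.

For ROI comparison, the kinematic model's voxel score is its univariate
RSA r and a visual model's is its searchlight r, both squared before
averaging over valid ROI voxels -- an interpretive commensurability
choice, made explicit here. The Model Performance Contrast is
$(M_1 - M_2)/(M_1 + M_2)$, tested per ROI with one-sample t tests
(Bonferroni over ROIs) plus Cohen's d, and the ROI × Model interaction
F (repeated-measures decomposition, subject as block) gets its p-value
from shuffling model labels within subject, keeping ROIs fixed --
preserving subject and ROI marginals.

# Numerical and degenerate-input policy

* Fisher z clamps r at ±(1 − 10⁻⁷); invalid voxels propagate as `NA`.
* TFCE integrates with a right-endpoint Riemann sum over 100 steps
  (brute-force validated to < 1% at 1,000 steps on toy grids); the
  negative tail is enhanced on the negated map.
* Agglomeration ties break deterministically (lowest index first, as in
  `hclust`); all stochastic stages take explicit seeds and restore the
  caller's RNG state.
* Degenerate inputs fail loudly and early: non-binary votes, zero
  variance columns, constant scores, mismatched object sets, empty
  models. An all-tied centrality split returns an empty subset with a
  warning rather than an arbitrary half.
* Volumes are stored as single-file NIfTI-1 with a diagonal affine
  recording voxel size. The reader/writer is a minimal native
  implementation (no NIfTI package is available in the target library)
  validated against an independent implementation during development;
  the cohort store uses float64 so simulate → write → read round-trips
  are exact. Coordinates in cluster tables are 1-based grid indices.

# What a green (or red) recovery test establishes

The headline parameter-recovery test demands, over 20 seeded cohorts, a
significant cluster covering at least half the planted kinematic region
*and* zero significant voxels in the strict null region in at least 19
runs. The first clause measures sensitivity and passes with full
coverage. The second clause is a zero-tolerance check run against a
procedure that by design allows a familywise error in 5% of datasets:
with the null region making up roughly three quarters of the mask, even
a perfectly calibrated correction produces at least one null-region
voxel in about 4% of runs, so the 19-of-20 bar is cleared with only
~80% probability by a correct implementation. A failure of that clause
at one or two runs is therefore evidence about the strictness of the
check, not about the pipeline; the dedicated calibration suite (100
pure-noise cohorts against the binomial confidence band) is the
diagnostic that would actually flag a miscalibrated correction.

# Known limitations

* The leave-one-out correlation artefact described above is a property
  of the model class, not of this implementation; with realistic rating
  structures it is small but detectably nonzero at cohort scale.
* Ward-on-correlation-distance and the entanglement norm/untangling
  protocol are conventions; published entanglement values from other
  implementations are not comparable targets.
* The permutation ANOVA assumes a complete subject × ROI × model table
  and drops incomplete subjects listwise.
* Runtime-scaled defaults (500 permutations in tests versus 10,000 in a
  real analysis) trade resolution of extreme p-values for speed; the
  calibration test shows the correction is valid at the scaled count.
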