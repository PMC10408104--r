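---
title: "Screening radiomic texture biomarkers in skeletal muscle: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening radiomic texture biomarkers in skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotexture)
```

## The problem

Dixon-weighted MRI yields co-registered water and fat contrast images, from
which both the composition (fat fraction) and the texture of skeletal muscle
can be quantified. In predominantly healthy cohorts, muscle tissue is far
more homogeneous than the tumour tissue radiomics was developed for, so
naively extracted feature sets are massively redundant and many features are
irreproducible. The screening problem is therefore: out of ~1000 candidate
texture descriptors per contrast, find the small subset that is (a) not a
duplicate of another feature, (b) reproducible between anatomically
symmetric regions, (c) not collinear with the rest, and (d) actually
informative about tissue state — then rank that subset and verify the
ranking predicts out-of-fold.

Age, body mass index and muscle fat fraction serve as auxiliary targets:
they are not the clinical endpoint, but they are tissue-state correlates
available in any cohort, so selection against them finds features that carry
physiological signal.

## Pipeline and parameters

The stages and every tunable that matters:

| stage | parameter | default | why |
|---|---|---|---|
| component pruning | relative size threshold | 0.025 | components below 2.5% of the label's largest component are segmentation noise |
| erosion | radius (voxels) | 1 | excludes boundary partial-volume voxels from texture estimation |
| resampling | target spacing | 3 mm isotropic | common denominator of the acquisition (1.2 mm in-plane, 3 mm slices) |
| normalization | z-score scale | 100 | intensity units are arbitrary; a fixed scale makes the bin width meaningful |
| discretization | fixed bin width | 25 | ~10–40 gray levels over a muscle ROI at scale 100 |
| LoG variants | sigmas | 1, 3 mm | a fine and a coarse blob scale around the voxel size |
| wavelet | coiflet-1, 1 level | 8 sub-bands | low/high-pass per axis on the original grid (undecimated) |
| clustering (I) | distance cut on 1−&#124;ρ&#124; | 0.1 | merges features correlated above 0.9 in magnitude |
| reproducibility (II) | mean left/right r | 0.7 | below this, a feature mostly reflects noise, not tissue |
| VIF pruning (III) | threshold | 10 | the conventional bound for harmful multicollinearity |
| shadow selection (IV) | forest; iterations; α | 100 trees, depth 5; 50; 0.05 | permuted copies calibrate the importance null |
| ranking (V) | forest; repeats | 100 trees, depth 8; 10 | importance measured as validation R² drop per permutation |
| evaluation | forest; top-k | 500 trees, depth 10; 10 | multi-class subgroup prediction, micro-averaged OvR AUC |
| cross-validation | folds | 5 | selection depends on subjects; folds expose that variability |

Subgroup bins: age uses interior edges 30/40/50/60/65 years (six bins), BMI
20/22.5/25/27.5/30/35 kg/m² (seven bins), and fat fraction six equal-width
bins over the observed central 95% range; values beyond the outer edges are
clamped into the first/last bin. The Bonferroni thresholds follow from these
counts: 0.05/10 = 0.005 for ten concurrent features, 0.05/6 ≈ 0.008 and
0.05/7 ≈ 0.007 for the sex comparisons per bin, and chance accuracy is
100/n_bins (16.67% for six, 14.29% for seven).

## What the synthetic cohort emulates — and what it does not

`generateCohort()` draws age uniform on [20, 69] years, sex Bernoulli
(51.4% male), per-sex lognormal heights, and lognormal BMI calibrated to
mean 26.81, sd 4.71 kg/m²; weight is derived so BMI = weight/height² holds
exactly.

`generatePhantom()` builds a 32³-voxel grid (3 mm spacing) with four
bilateral ellipsoidal "muscles" whose right sides mirror the left about the
mid-sagittal plane exactly — a property the tests exploit. Inside each
muscle, the voxelwise fat proportion is

```
ff = intercept + ageCoef·(age−45) + bmiCoef·(bmi−26.8) + subject offset
     + amplitude·GRF(corrLength) + voxel noise, clipped to [0,1],
```

and intensities are water = S·(1−ff), fat = S·ff, so with all noise terms
zero the voxelwise fat fraction equals the model prediction exactly. The
texture component is a Gaussian random field whose correlation length grows
with age (3.5 mm + 0.06 mm/year about age 45) and whose amplitude carries a
per-subject lognormal multiplier (sd 0.5 on the log scale) shared by both
sides and all muscles. The per-muscle intercepts (0.279, 0.234, 0.121,
0.199 for gluteus, psoas, extensors, adductors) sit at typical in-vivo
fat-fraction levels; the subject-level offsets (sd 0.05–0.06) reproduce the
several-percentage-point between-subject spread seen in real muscle and are
what makes left/right reproducibility a meaningful filter: shared drivers
(composition, granularity) survive step II, purely stochastic texture
realizations do not. No quantitative texture model of real muscle was
available to calibrate against, so these texture parameters are the
package's own choices, fixed once and documented here.

The phantom deliberately omits coil bias fields, Dixon reconstruction
physics, anatomical muscle shapes, field-of-view truncation and
inter-muscle contamination. Passing tests on the phantom therefore
demonstrate that the pipeline's statistics behave as specified (selection
recovers planted structure, error rates are nominal, determinism holds) —
not that any particular feature is a biomarker in vivo.

`generateFeatureTable()` skips imaging entirely and plants tabular
structure: correlation blocks via a shared latent factor per block (which
guarantees a positive semi-definite correlation structure), per-feature
left/right reliability r (sides are `sqrt(r)·latent + sqrt(1−r)·noise`, so
the side-level correlation is exactly r and block correlations attenuate to
r·ρ), and target-linked features with stated standardized effect sizes.
This is the workhorse for the cascade's statistical property tests.

## Numerical and design choices

* **Texture matrix aggregation.** Co-occurrence and run-length counts are
  accumulated over the 13 unique 3-D directions into a single matrix
  ("merged" aggregation) before feature computation, rather than averaging
  per-direction feature values. Both are standard; merging is faster,
  deterministic, and makes the transposition-symmetry property exact.
* **Catalog decomposition.** 1015 features per contrast decompose as
  (18+22+16+16+5+14) texture features × 11 variants + 14 shape features.
  Shape features are computed once per muscle/side from the *uneroded*
  pruned mask (erosion is texture hygiene, not morphology) and are tagged
  contrast-invariant; they are carried in both contrasts' tables.
* **Surface area.** Computed from a Gaussian-mollified indicator via the
  coarea formula (sum of gradient magnitudes × voxel volume). On a
  digital sphere of radius 20 voxels this is within 2% of 4πr², which a
  naive exposed-face count misses by ~50%.
* **LoG filters.** Separable second-derivative-of-Gaussian kernels with the
  DC component removed (a constant image maps to exactly zero) and
  scale normalization in voxel units; sigmas below the voxel size are
  usable but increasingly discrete.
* **Step-I clustering.** `hclust(method = "centroid")` on 1−|ρ| with a
  merge-order traversal for the cut: equivalent to `cutree` when heights
  are monotone and well-defined under centroid inversions. Absolute
  correlation is used so anti-correlated duplicates merge; representatives
  are chosen original > LoG > wavelet, alphabetical within a tier —
  alphabetical tie-breaks are used everywhere for reproducibility.
* **Ranking normalization.** Within a selected set of N features the
  0-based sorted position maps to p/(N−1), so the first feature ranks 0 and
  the last 1 (a singleton ranks 0; ties share mean positions). An
  alternative normalization dividing by N instead of N−1 does not reach the
  0/1 endpoints and was rejected in favour of the endpoint convention;
  features unselected for a target contribute rank 1 for that target.
* **Side combination.** After step II a feature's subject-level value is
  the mean of its left and right values (configurable to left-only); in the
  joint all-muscles scope, values are additionally averaged over the four
  muscle groups and the FF target is the mean of per-muscle FFs.
* **Forests.** All forests are `ranger` with fixed seeds and one thread.
  The classification forest uses Gini impurity splits — the conventional
  impurity criterion available in the R forest implementations; with 500
  trees of depth 10 the practical difference from an entropy criterion is
  negligible.
* **Shadow selection.** Decided features leave the pool; the loop stops
  early when nothing is tentative. Features undecided after 50 iterations
  are rejected (conservative). The confirmation test is a two-sided
  binomial test on hits against chance 0.5 at α = 0.05, Bonferroni-adjusted
  for the number of features entering the selection, and at least five
  shadow attributes are always kept. Both safeguards matter: with only one
  or two freshly permuted shadows late in a run, a feature whose *fixed*
  spurious correlation with the target survived the early rounds beats them
  persistently, and without the multiplicity adjustment such features are
  falsely confirmed at well above the nominal rate.
* **Degenerate inputs.** Constant grids cannot be normalized (error);
  zero-variance features are flagged and excluded from correlations; masks
  emptied by erosion yield flagged missing values, never silent zeros;
  perfectly collinear features are removed first with infinite VIF; an
  empty selected set is a valid step-IV outcome.
* **Micro-averaged OvR AUC.** All (class, sample) pairs are flattened into
  one ROC; with exactly two classes the two complementary columns are a
  single binary problem and are not double-counted.

## Problem sizes

The test-suite simulations use cohorts of 300–600 subjects for classifier
properties, 1000–2000 subjects × 12–21 features for the selection-cascade
properties (50 null repetitions for the false-selection rate, 5000
repetitions for the rank-test calibration), and a 300-subject, 32³-voxel
phantom cohort for the end-to-end demonstration — sizes at which the
Monte-Carlo tolerances quoted in the tests (±0.05 on correlations, ±0.01 on
test size, ±0.05 on null AUC) hold comfortably.

## Known limitations

* The phantom's texture model is a smoothed Gaussian field; it has no
  fibre anisotropy, so direction-sensitive features carry less structure
  than in vivo.
* Shape features are voxel-based approximations (mesh volume equals voxel
  volume; in-plane maximum diameters are computed on projections).
* Step-IV/V forests are not tuned; the defaults above are part of the
  method definition, not optimized hyperparameters.
* Segmentation itself is out of scope: masks are inputs, produced upstream
  by whatever segmentation tool the user trusts, and the manual
  accept/reject decision of the consistency check stays manual — the
  package only renders the overlays.
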