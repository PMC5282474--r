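---
title: "Dual-tracer phantom PET analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-tracer phantom PET analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`dualpet` implements the analysis chain used in preclinical dual-tracer PET
studies of neuroinflammation and amyloidosis in transgenic mouse models:
reference-region SUVR quantification, whole-brain voxel-wise group
statistics with FDR thresholding, four-category tracer-overlap mapping with
percent occupancy and Dice coefficients, and terminal fluid-biomarker
association statistics. Because such studies rarely deposit raw images, the
package also ships a parametric 3D phantom generator that reproduces the
*statistical structure* of this study class, so the whole pipeline is
exercisable and testable end to end without any download. Registration,
reconstruction and radiochemistry are out of scope: all images are assumed
already co-registered on a common grid.

## The phantom generator

### Geometry

The atlas is parametric: a brain ellipsoid (about 1.1 cm³ at the default
0.4 mm isotropic grid) containing box/ellipsoid regions named for the
anatomy they stand in for — frontal, parietal and piriform/entorhinal
cortices, hippocampus, thalamus, cerebellum, brainstem, and two
white-matter reference regions. Three VOI volumes are treated as contracts
and hit by growing or trimming regions in whole voxels: 29 mm³
(cerebellar/brainstem white-matter reference used for the TSPO tracer),
67 mm³ (pons/midbrain/hindbrain white-matter reference used for the amyloid
tracer) and a 156 mm³ composite forebrain target
(frontal + parietal + hippocampus + thalamus). Reference regions are claimed
first and are therefore disjoint from every target region. The default grid
(0.4 mm isotropic, 36×51×31) is finer than a typical small-animal PET
reconstruction (≈0.8 mm) so that voxel-wise statistics have nontrivial
spatial support; it is configurable, with an explicit sizing error naming
the first VOI that no longer fits.

### Pathology model

Let `a` be age in months. Amyloid burden in transgenic (TG) animals follows
a per-region *hinged logistic*,

    b_r(a) = amp_r * max(0, 2 * plogis(growth * (a - onset_r)) - 1),

which is exactly zero up to the regional onset age and saturates at `amp_r`.
Onsets run from 6.0 months (frontal cortex) through 14 months (cerebellum),
so amyloid is absent at 5 months, focal and frontal at 8 months, and
widespread by 13–16 months. Wild-type (WT) amyloid burden is identically
zero. Inflammation burden is the sum of (i) a *diffuse* component — a
cortex-weighted, Gaussian-smoothed (2 mm FWHM) regional topography gated by
an early-onset ramp (onset 3.5 months, rate 0.25/month), (ii) a
*plaque-associated* component proportional (weight 0.8) to the local amyloid
burden, and (iii) a small linear WT aging drift (0.004/month) applied to
both genotypes outside the reference regions. This encodes the temporal
dissociation the package is designed around: glial activation is already
established at the youngest age while fibrillar amyloid is not, and the two
signals converge spatially late in life.

An image is `1 + k * burden` inside the brain (so the expectation in the
reference regions is exactly 1), with `k = 0.35` for the TSPO tracer and
`0.75` for the amyloid tracer, plus additive Gaussian voxel noise
(SD 0.05). Per-animal heterogeneity is a shared lognormal multiplier
(log-SD 0.20) entering the two tracers with different exponents (0.8 for
inflammation, 2.0 for amyloid): plaque load varies across animals much more
than glial activation does, which is what pushes the amyloid
standardized-difference curve below the TSPO and sTREM2 curves.

The voxel noise is spatially correlated (Gaussian-shaped, 1.2 mm FWHM by
default, rescaled to keep the marginal SD). The smoothness of real
reconstructed µPET noise is not well characterised, so the correlation
length is an explicit free parameter; a positive default was chosen because
perfectly independent voxel noise makes VOI means unrealistically precise
(averaging ~2400 voxels would shrink the SUVR noise floor to ~10⁻³), which
distorts group SDs and hence standardized differences.

### Terminal biomarkers

Each animal's terminal biomarkers are monotone functions of *that animal's
own* forebrain burden: `b = base * (1 + c * B) * exp(cv * z - cv² / 2)`
with mean-one lognormal noise. sTREM2 and the cytokines (IL-1β, IL-6,
KC/GRO) couple to the forebrain inflammation burden, total Aβ to the
amyloid burden. Couplings and CVs are per-biomarker parameters; sTREM2 is
deliberately the cleanest (coupling 5.0, CV 0.07), the cytokines the
noisiest (CV 0.25), reproducing the observation that sTREM2 tracks imaging
far better than common cytokines. Because the coupling is linear rather
than a correlation coefficient, the population Pearson R between sTREM2 and
TSPO SUVR is *implied* by the model; tests recover it by simulating the
generator at large n and checking Fisher-z confidence-interval coverage at
small n.

### Reproducibility

Every animal owns an independent random substream derived by an integer
mixer from the master seed and the animal's identity (genotype, age,
replicate), so cohort regeneration is bit-identical under a fixed seed and
does not depend on enumeration order; the two tracer images of one animal
share the same burden multiplier.

## Quantification

SUVR is the arithmetic (untrimmed) mean of the target VOI divided by the
arithmetic mean of the tracer-specific white-matter reference; trimming is
not offered because standard SUVR practice in this study class uses plain
means. SUVR is invariant to global image rescaling — that is the point of
reference scaling — and the reference VOI against itself is exactly 1.
Group summaries use the unbiased (n−1) SD and refuse singleton cells.

## Voxel-wise statistics

The group contrast is a pooled-variance two-sample Student t (TG − WT) per
brain-mask voxel with df = n₁ + n₂ − 2, requiring equal group sizes (the
balanced design this mapping convention assumes). The binarized contrast is
one-sided (TG elevated); a two-sided option exists behind a flag. Voxels
with zero pooled variance are assigned t = 0, p = 1 and counted in a
message. Multiple comparisons are handled by Benjamini–Hochberg step-up
over brain-mask voxels only, with standard tie behaviour (every voxel with
p equal to the largest rejected p is rejected); the rejection set is
reported as the equivalent t threshold — the smallest rejected t, `+Inf`
when nothing survives. No cluster-extent or random-field correction is
applied, and no voxel-level covariate GLM is offered: the design is a pure
two-group contrast per age. Under the default spatially correlated Gaussian
noise the voxel p-values are positively dependent (PRDS), for which BH
retains its FDR guarantee. Optional pre-statistics Gaussian smoothing is
available (`fwhm_mm`), default off, implemented as separable convolution in
mm units with symmetric boundary reflection (which preserves the image
sum); NaN marks out-of-mask voxels in exported maps.

## Overlap analysis

Per age, the two binarized maps combine into the fixed four-category code
(0 neither, 1 TSPO only, 2 amyloid only, 3 both); percent occupancy is each
category's share of the whole brain mask, which always partitions 100%.
The whole-brain denominator is the atlas brain mask. Binary Dice is
`2|A∩B| / (|A| + |B|)` (0 when both maps are empty, with a message).

For the agreement of the *non-binarized* t-maps there is no single standard
definition; this package adopts the fuzzy (min-based) Dice on positive
parts, `2 Σ min(a⁺, b⁺) / (Σ a⁺ + Σ b⁺)`, because it reduces exactly to
binary Dice on 0/1 fields and weights agreement by regional effect
magnitude. It is deliberately isolated in one function
(`dice_continuous()`) so an alternative (e.g. multi-threshold level-set
Dice) can be swapped without touching the rest of the pipeline. One
consequence to keep in mind: two t-fields that are pure noise still share
positive excursions, so fuzzy Dice has a noise floor well above 0 — its
*increase* across ages, not its absolute value, is the interpretable
signal. Transition flows between consecutive ages are computed per tracer
(persisting / newly presenting / disappearing voxels, as percent of brain
volume, satisfying occupancy(to) = occupancy(from) + new − disappeared);
the full 4×4 category transition matrix is attached for completeness.

## Association statistics

* One-way ANOVA with Tukey HSD across ages (`aov` + `TukeyHSD`); with two
  groups the Tukey p reduces to the pooled two-sample t-test p.
* Normality screening is a Lilliefors-corrected one-sample KS test
  (`nortest::lillie.test`), since no reference distribution with known
  parameters is available; this requires n ≥ 5. This is a documented
  deviation risk when comparing with analyses that used an uncorrected KS
  test against fixed parameters.
* Pearson correlation with the usual two-sided t-based p.
* Multiple regression on z-scored (n−1 SD) outcome and predictors, so the
  reported coefficients are standardized β; with a single predictor
  β² = R². The default modelling convention is *two separate* age-adjusted
  models (sTREM2 ~ TSPO SUVR + age; sTREM2 ~ amyloid SUVR + age) rather
  than one joint model, because the two imaging endpoints are strongly
  collinear in this design; a joint model can be fit by passing both
  predictors.
* Standardized differences: `d(a) = (mean_TG(a) − wt_interp(a)) / SD_TG(a)`
  where `wt_interp` is the straight line through two WT (age, mean)
  anchors — the assumption that control measures develop linearly during
  aging — extrapolated when a TG age lies outside the anchors (plain
  reading of the linearity assumption). When a time point's own SD is
  unusably small, the pooled SD of two adjacent TG ages
  (`pooled_sd()`, the combined-SD approximation) can replace both; the
  pipeline applies this by default to total Aβ at the two youngest ages.
* Group-size planning inverts the exact noncentral-t power computation
  (`power.t.test`) to the smallest integer n per group reaching the target
  power, floored at n = 2.

## Numerical conventions and degenerate inputs

Tolerances follow from the operations: overlap algebra identities hold to
1e−9, oracle comparisons to 1e−10…1e−12. Degenerate inputs fail loudly and
early: empty masks, non-positive reference means, unequal group sizes,
singleton cells, constant samples, zero SDs without the pooling flag,
same-age transition inputs, rank-deficient regressions (naming the
collinear set), and undersized grids (naming the first VOI that does not
fit).

## What passing tests do and do not show

The phantom reproduces the *statistical shape* of this study class — group
structure, monotone regional progression with realistic between-animal
heterogeneity, reference-region logic, coupled terminal biomarkers,
spatially correlated noise. It does not simulate PET physics (attenuation,
scatter, partial volume, decay), registration error, anatomical variation,
ventricles, or non-Gaussian reconstruction artefacts. Tests passing on the
phantom therefore validate the *analysis implementation* and its
statistical properties (FDR control, estimator recovery, algebraic
identities), not the biological accuracy of any particular real-world
dataset. Absolute phantom outputs (e.g. occupancy percentages) are not
calibrated to match any published cohort's printed values — only the
qualitative progression pattern is designed in.

## Problem sizes used by the test-suite simulations

Chosen as the package's own trade-off between statistical resolution and
desk-scale runtimes: FDR control is checked on 200 null cohorts (N = 8 per
genotype, one age, one tracer) against q + 3 Monte-Carlo SEs; coupling
recovery on 200 replicate TG cohorts of 24 animals against the model-implied
correlation estimated from a 500-animal cohort; regression recovery on 500
replicates at n = 25; the ANOVA type-I rate on 2000 replicates; the
end-to-end progression pattern on the full default design (2 genotypes × 4
ages × 8 animals × 2 tracers = 128 images).

## Known limitations

* The fuzzy-Dice noise floor (above) makes early-age continuous Dice
  values incomparable across noise models.
* The Lilliefors p-value approximation needs n ≥ 5.
* Atlas geometry is schematic; regional labels mirror anatomy in name and
  rough location only, and there are no ventricles (whether a forebrain
  VOI should exclude them is moot here but matters for real atlases).
* Equal group sizes are enforced; unbalanced designs would need a Welch
  variant that is intentionally not offered, to match the mapping
  convention this package follows.
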