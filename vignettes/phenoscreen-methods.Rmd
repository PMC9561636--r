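---
title: "Phenotypic profiling of neuronal high-content screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic profiling of neuronal high-content screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenoscreen)
```

## The problem

Disease-relevant phenotypes of iPSC-derived midbrain dopaminergic neurons
(mDANs) — elevated alpha-synuclein, reduced mitochondrial membrane
potential, sparser dendritic arbors, more compact mitochondria — are
individually subtle. phenoscreen implements the multi-feature alternative:
extract a fixed catalogue of per-well image features from multi-channel
384-well plate images, train a two-class reference classifier (wild-type
vs. mutant), and treat the classifier's decision value as a single
phenotypic axis. Compound-treated wells are then *mapped* into that
decision space: a well that scores toward the wild-type anchor has been
phenotypically rescued, and screening statistics (Z-factor, 3-SD hit
calling, replicate power) quantify whether single wells are detectable.

Because the study's raw images are not redistributable, the package
carries a first-class synthetic-data module with known ground truth. All
tests and the acceptance report run against that stated world.

## The feature catalogues

Each staining panel has a fixed manifest (`inst/extdata/catalogue_*.csv`,
reproducible from `build_catalogue()`): panel A
(Hoechst/aSyn/TH/MAP2) has exactly 126 features of which exactly 54 are
computed on the TH+ (dopaminergic) subpopulation; the mitochondrial panel
(Hoechst/calcein/TMRM) has 96; the LAMP1 panel is an analogous
package-defined catalogue of 82. Only the counts and the
figure-prominent features (aSyn intensity, aggregate area, TH+ count,
MAP2+ ratio, branch statistics, TMRM intensity, mitochondrial
compactness and form factor, LAMP1 surface area) are fixed requirements;
the remaining composition is a reconstruction — the original feature
tables are not published in the main text — built compositionally from
populations (field, nuclei, all cells, TH+, MAP2+, neurites,
mitochondria, lysosomes), channels, and statistic families (count,
intensity, morphology, texture, ratio).

## The synthetic generator

The generator is a *stated world*, not a tuning knob. Its defaults are
the observed effect sizes: mutant wells carry aSyn intensity ×1.15, TMRM
intensity ×0.67 (a 33% decrease), branch-related features ×0.7,
mitochondrial compactness ×1.2, and aggregate (pS129-like) area ×1.5.
Compound conditions interpolate the mutant profile toward control in log
space by a rescue fraction $\lambda \in [0,1]$ (so $\lambda = 1$
reproduces the control profile exactly and $\lambda = 0$ the mutant), and
may add compound-specific aSyn lowering (PEP005 ×0.85, prostratin ×0.75).

A well-level feature value is

$$x_{wf} = b_f \cdot e_{c(w),f} \cdot p_{\pi(w),f} \cdot \varepsilon_{wf},$$

baseline × condition effect × per-plate batch factor × noise. All noise
is multiplicative log-normal so intensity-like quantities stay positive:
`well_cv` (default 0.10) is the target well-to-well coefficient of
variation (the log-scale SD is $\sqrt{\log(1+cv^2)}$, mean-corrected so
the factor has expectation 1), `plate_batch_sd` (0.05) is the log-SD of
one factor per plate × feature — removable by per-plate median
normalization, which makes that step testable — and `field_cv` (0.15)
applies per simulated field before the arithmetic field-to-well mean
(9 fields per well, matching a 3×3 montage). With probability
`outlier_rate` (0.01) a well is corrupted by ×5 or ×1/5 on every feature.
The study parameterizes none of these; the values are this package's
choices, fixed once, and stated here rather than derived.

Plates are 16×24 with the edge ring excluded (308 usable wells); spiked
compound wells (six per compound by default) are drawn uniformly without
replacement from the mutant-DMSO wells. Ground truth (applied factors,
outlier and spike flags, rendered object counts and positions) is
returned as a separate object; the feature table itself carries only the
plate-map metadata.

The image renderer draws nuclei as smoothed elliptical blobs, somata as
discs, neurite trees as piecewise-linear trunks with a known number of
side branches, punctate aSyn aggregates inside somata, and (mitochondrial
panel) elongated puncta on a smooth background gradient, followed by a
Gaussian PSF and Poisson photon noise. It deliberately does **not**
emulate uneven staining, touching cells, debris, saturation, or focus
drift — so a green round-trip test establishes that segmentation recovers
what was drawn, not that it would survive real microscopy. Ground truth
for branch points counts only junctions actually rendered inside the
frame (trees may exit the field).

## Image analysis

Segmentation is deliberately classical and deterministic:

* illumination correction divides by a large-σ Gaussian flat-field
  estimate (default σ = min(height, width)/8) and rescales to preserve
  the mean;
* per-plate automatic thresholds are Otsu on a pooled pixel sample —
  a reproducible stand-in for "empirically determined per plate". When
  the between-class variance plateaus across an empty histogram valley,
  the plateau midpoint is taken;
* somata are reconstructed as fixed-radius nearest-nucleus discs
  (default 8 px) around segmented nuclei; marker positivity (TH+, MAP2+)
  is an Otsu cut on per-cell mean soma intensity, with degenerate
  (near-constant) intensity vectors yielding all-negative calls;
* mitochondria/lysosomes/aggregates: rolling-ball background subtraction
  (grayscale opening with a ball-topped structuring element, radius
  15 px), white top-hat (disc radius 5 px; 3 px for aggregates), then a
  robust threshold (median + 6·MAD of the top-hat image — scale-free, so
  a blank gradient field yields zero objects) and a minimum-area filter
  (4 px²). The study reports no radii; these defaults are sized to the
  synthetic optics and exposed in `seg_params()`;
* neurites: the cell-marker mask minus an enlarged soma disc
  (1.35 × soma radius, so the blurred soma rim cannot masquerade as a
  neurite loop) is thinned (Zhang–Suen) and pruned by 4 end-point
  iterations to suppress raster spurs. Branch points are skeleton pixels
  with ≥ 3 neighbors, merged within ~2 px so one junction is counted
  once; end points have exactly one neighbor; total length is the
  skeleton pixel count.

Morphometry: perimeter uses the 4-direction Crofton estimate (close to
the true contour for smooth objects, ~2L for thin lines, so digitized
discs have form factor ≥ 0.85 and 1-px lines ≤ 0.2); form factor is
$4\pi A/P^2$ capped at 1 + ε for discretization; compactness is defined
as $A/(\pi r_{max}^2)$ with $r_{max}$ the maximum centroid-to-border
distance — the source material never defines it, and this choice is
bounded (1 for a disc) and monotone in elongation; eccentricity comes
from second central moments with a 1/12 pixel-variance correction, so it
stays strictly below 1.

Field-to-well aggregation is the arithmetic mean; a feature whose
population is absent in one field is averaged over the fields where it
exists and is `NA` only when absent everywhere.

## Preprocessing

Fixed order: normalize → outlier removal → decorrelation (the original
order is unstated; this one makes the normalization target well-defined
for the outlier statistics). Normalization divides every feature by the
plate's median over reference-condition wells (division, not
subtraction, because control-centered fold values are the natural axis
scale); features with non-positive reference medians are dropped and
logged. Outlier wells are removed by a robust vote: per plate ×
condition, robust z = (x − median)/(1.4826 · MAD) per feature, and a
well is removed when more than 20% of features exceed |z| > 3.5
(zero-MAD features abstain). Correlated features are pruned greedily in
catalogue order at |Pearson r| ≥ 0.9 — the threshold and keep-first rule
are package choices; catalogue order is the only canonical ordering
available. Every step's report is replayable (`replay_prep()`
reproduces the processed table bit-exactly).

## Classification and the decision axis

`train_reference()` repeats a stratified 80/20 shuffle split 25 times;
within each repeat the hyperparameters are chosen by 5-fold CV accuracy
on the training portion (SVM: linear kernel, C ∈ {0.01, 0.1, 1, 10};
LDA: ridge λ; GBM: trees 100/300 × depth 3/5 × learning rate 0.05/0.1),
features are standardized on the training split (zero-variance features
are ignored rather than erroring), and test accuracy is recorded —
reported as mean ± SEM = SD/√25. The linear kernel is chosen because
the decision axis is plotted and interpreted linearly and leave-one-out
attribution assumes feature-level interpretability; no kernel is named
in the source material.

No SVM, boosted-tree, or discriminant package being available in the
target environment, the learners are authored here: the SVM is
liblinear-style dual coordinate descent on the L1 (hinge) loss with an
augmented bias column, the LDA a pooled-covariance discriminant with a
small ridge on the covariance (so p > n and collinear features are
well-defined), and the GBM a logistic gradient-boosted exact-split
regression-tree learner with Newton leaf values.

A well's **raw score** is the ensemble mean of the 25 fits' signed
decision values (log-odds for GBM) — reusing the CV fits rather than
refitting once mirrors how per-well classification distributions are
shown as boxplots. The **normalized score** is the affine map taking the
negative-class raw-score median to 0 and the positive-class median to 1
(anchors estimated on the training table). Whether the plotted axis in
the source material is a probability, discriminant or distance is never
stated; this anchor convention is a reconstruction with the property
that reference classes sit at 0 and 1 by construction and any condition
can be mapped without retraining.

## Screening statistics

* **Z-factor**: $Z = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ with
  sample (n−1) SDs; equal means yield a flagged −Inf sentinel.
* **LOOCV attribution**: each kept feature is left out once, the model
  retrained with the *same* CV seed (so ΔZ reflects feature removal,
  not resampling noise), and ΔZ = Z_full − Z_without reported.
  Duplicated features null each other's ΔZ, which is the expected and
  tested behaviour.
* **Hit calling**: median (not mean) of the reference scores as center,
  sample SD as scale, hit iff |score − m| > k·s with k = 3. The calls
  carry a direction; for rescue screens the flag of interest is a hit
  *toward the control side*. In the synthetic world the null score
  distribution is measurably right-skewed (multiplicative feature noise
  through a linear classifier), so the upward 3-SD tail runs near 0.9%
  (still below the 1% bound) while the downward (rescue-direction) tail
  is clean — the spiked-well acceptance test therefore counts
  directional flags, consistent with the directional default of the
  power analysis.
* **Replicate power**: for n replicates of a condition shifted d
  reference-SDs, success = at least one well beyond k·SD from the null
  median in the shift direction (two-sided by flag). The default
  estimator is Monte Carlo as specified; for the normal null an
  `method = "analytic"` path evaluates the exact geometric form
  $1-(1-p)^n$, $p = \Phi(d-k)$ (directional) — the Monte-Carlo minimal
  n is undefined to ±1 when the target power falls within simulation
  error of a boundary (at d = 2, k = 3, target 0.85 the true power of
  n = 11 exceeds the target by 4·10⁻⁴), and the analytic path resolves
  exactly those boundaries.
* **Group tests**: two-sided Mann-Whitney U (exact where ties permit)
  or Welch's t; `auto` uses Welch only when both groups pass
  Shapiro-Wilk at p > 0.05. Bootstrap percentile CIs of the median use
  1000 resamples.

## Numerical and design notes

* Determinism: every stochastic stage derives a private stream from
  (seed, stage tag) via a 32-bit hash, so layouts, tables, renders,
  splits and bootstraps are reproducible independently of call order,
  and the C++ SVM shuffles with its own LCG rather than R's RNG.
* The replicate-power example in the source material ("effect size 2 at
  power 0.85 requires at least four replicates") is inconsistent with
  the normal-null closed form (n = 11); it was computed on the study's
  empirical score distribution, which is not available. The package
  validates against the closed form and accepts empirical nulls as
  input; the "four" is deliberately not asserted anywhere.
* Catalogue counts (126/54/96) are enforced at load time and in tests;
  the LAMP1 catalogue count (82) is package-defined.
* TIFF I/O is a minimal baseline dialect (uncompressed 16-bit grayscale
  little-endian, one strip) written and read by the package itself, as
  no TIFF-capable R package is available in the target environment.

## Known limitations

Segmentation is tuned to the cartoon renderer; real micrographs would
need parameter re-estimation and likely watershed splitting of touching
nuclei. The LOOCV attribution retrains once per feature and is O(p) in
training cost. The GBM exists for algorithm parity and is slower than
the compiled SVM path. PaCMAP embedding is out of scope (PCA only).
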