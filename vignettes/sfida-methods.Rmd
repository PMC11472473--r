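---
title: "Methods: single-particle immunoassay quantitation with sfida"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle immunoassay quantitation with sfida}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfida)
```

## The assay and its readout model

Surface-based fluorescence intensity distribution analysis (sFIDA) is a
sandwich immunoassay with a microscopy readout. Capture and detection
antibodies are directed against the same or overlapping epitopes of the
analyte, so monomeric protein — whose single epitope is masked by the
capture antibody — produces no detection signal, while aggregates
presenting the epitope many times bind labelled detection antibodies and
appear as diffraction-limited fluorescent particles on the glass surface.
The surface is imaged by total internal reflection fluorescence microscopy
(TIRFM): 25 fields of view per well, each 1000 × 1000 pixels in 14-bit
grayscale.

The readout is deliberately primitive: the **pixel count**, the number of
pixels whose intensity exceeds a cutoff anchored in the blank control.
No spot segmentation, localization, or intensity integration enters the
readout; aggregates of different size simply light up different numbers
of pixels. All downstream quantities — calibration, limit of detection,
diagnostic statistics — are functions of pixel counts.

### Cutoff determination

All accepted images of the blank-control wells (unspiked sample buffer)
on a plate are pooled, and the cutoff is the smallest integer intensity
$c$ such that the fraction of pooled blank pixels strictly greater than
$c$ is at most $10^{-5}$ — i.e. 0.001 % of blank pixels remain positive.
Two conventions are fixed here and used consistently:

* **strict inequality** at the cutoff: a pixel exactly at $c$ counts as
  negative ("remain positive" reads as "above");
* **per-plate pooling** of every accepted blank image. Pooling scope is a
  genuinely open choice (per-image thresholding would also satisfy the
  rule); pooling uses all $\geq 2\times10^7$ blank pixels to estimate a
  $10^{-5}$ tail, where a single image's $10^6$ pixels would make the
  achieved fraction very granular.

Because the rule operates on the pooled empirical distribution, it is
distribution-free: no Gaussian assumption enters the cutoff itself (the
synthetic generator happens to use Gaussian read noise, the rule does
not know that).

### Well and sample aggregation

Pixel counts of a well's accepted images are summed and rescaled to the
nominal image number: with $k$ of $n$ images accepted the well readout is
$\text{raw sum} \times n/k$. Summing versus averaging is another open
convention; the rescaled sum keeps wells with excluded images comparable
to complete wells while preserving the "counts per 25 images" scale of
everything downstream (LoD, calibration). Wells with fewer than 60 % of
images accepted, or none, are flagged invalid rather than silently
reported as zero.

Samples are applied in 4-fold determination. Per sample we report the
replicate mean, the $n-1$ sample standard deviation, and CV% =
$100\,s/\bar x$, gated at **20 %** for synthetic species (calibration
standards, oligomer quality controls) and **25 %** for fecal samples.
The CV of a zero-mean sample is flagged as undefined, not computed.

### Image quality control

The original exclusion of artifact-bearing and out-of-focus images was
operator-driven; here it is automated with two stated heuristics whose
thresholds live in `qc_params()`:

* **artifact**: fraction of saturated pixels $> 10^{-3}$, or a bright
  connected component (pixels above 90 % of the intensity range) larger
  than 500 px;
* **defocus**: focus score below 0.1, where the score is
  $\mathrm{Var}(\nabla^2 I)/\mathrm{Var}(I)$, the variance of the
  discrete 4-neighbour Laplacian normalized by the image variance.

The normalization matters. Pure read noise scores $\approx 20$ (the
Laplacian kernel amplifies white-noise variance 20-fold), in-focus spot
fields land at a few tenths (spot energy dominates both numerator and
denominator), and defocused spot fields fall well below 0.05 because blur
inflates the image variance while contributing almost no high-frequency
energy. The default 0.1 therefore separates defocused fields from both
blanks and in-focus fields by an order of magnitude on either side.

## Calibration and limit of detection

Silica nanoparticles (SiNaPs) coated with amyloid-β epitopes serve as
countable, size-defined aggregate mimics. A standard concentration is
included in the curve only if

1. its replicate pixel counts exceed the blank replicates by a one-sided
   Mann–Whitney U test at $\alpha = 0.05$ (exact null distribution up to
   8 replicates per group without ties, normal approximation with
   midranks otherwise), and
2. it lies in the linear range.

"Linear range" has no published operational definition, so the package
states one: starting from all significant points, the highest remaining
concentration is dropped while its relative residual from a
$1/y$-weighted refit on the points below it exceeds 20 %; trimming stops
at three points. This captures saturation roll-off at the top of the
series while never discarding interior points.

The curve is weighted least squares of mean pixel count $y$ on nominal
concentration $x$ with weights $1/y$ — the observed mean readout per
point, so a point with half the signal carries twice the weight, which
counteracts the roughly signal-proportional variance of counts. Points
with $\bar y \le 0$ are unweightable and excluded.

Concentrations are recovered by inverting the line,
$(y - b)/m$; negative values (readouts below the fitted blank level) are
clamped to zero and flagged `below_blank` rather than reported negative.

The limit of detection uses 24 blank replicates:

$$\mathrm{LoD} = \overline{\text{pixel count}}_{BC} + 2\sigma,$$

with $\sigma$ the $n-1$ sample SD of the blank **well-level** pixel
counts (not the pixel-level SD — the LoD asks when a *well readout* is
distinguishable from blank wells), converted to fM through the curve.

## Analytical-validation metrics

All validation arithmetic is centralised and unit-free:

* **percent signal reduction** $= 100 - 100\,\bar y_{ctl}/\bar y_{ref}$,
  used identically for selectivity controls (no capture antibody, no
  detection probe, off-target detection probe) and immunodepletion;
* **dilution linearity** at point $i$, relative to the least-diluted
  anchor: $100\,(y_i f_i/f_0)/y_0$ on blank-corrected readouts, accepted
  in the inclusive 80–120 % band per point and on the mean over
  non-anchor points. The anchor convention is stated, not inherited: the
  alternative (per-step ratios) averages differently, and relative-to-
  anchor is scale-invariant either way;
* **spike recovery** $= 100 \cdot \text{net measured}/\text{nominal}$,
  with negative net readings reported as-is and flagged;
* **stability** normalized to baseline with an inclusive ±25 % band
  (75 % and 125 % pass);
* **inter-assay agreement** by Spearman ρ on paired runs, midrank ties,
  exact permutation p below 10 pairs, gate ρ > 0.9.

Inclusive tolerance bounds are used throughout: a measurement exactly on
a stated limit passes.

## Cohort statistics

Calibrated concentrations are screened with four normality tests
(Shapiro–Wilk, Lilliefors, Kolmogorov–Smirnov against the sample-moment
normal, Anderson–Darling); any $p < 0.05$ routes the analysis to
non-parametric methods. The Lilliefors and Anderson–Darling tests come
from the `nortest` package (Dallal–Wilkinson approximation) rather than a
Monte-Carlo table of our own. Note the joint "all four pass" rate on
genuinely normal data is necessarily below $1-\alpha$ — four correlated
tests are applied — which is why the package's calibration tests check
each test's level individually.

The group comparison is a two-sided Mann–Whitney U test (two-sided as
the conservative reading; the tested hypothesis of elevated disease-group
levels would admit one-sided). Covariate screens (stool-consistency
score, age, fecal matrix biomarkers) use Spearman correlations, overall
and per group, with pairwise missing-data deletion.

ROC analysis takes the disease group as positive with the decision rule
"concentration ≥ threshold ⇒ positive" (the orientation implied by
elevated disease-group levels; the inequality direction is our stated
convention). Candidate thresholds are midpoints between consecutive
distinct values plus $\pm\infty$; the trapezoidal AUC then equals the
tie-corrected $U/(n_1 n_2)$ identically, which the test suite asserts on
random data. The operating point maximizes Youden's
$J = \text{sens} + \text{spec} - 1$; ties are broken toward **higher
specificity**, matching the screening context in which the assay's
published operating point favours specificity.

## The synthetic-data generator

No raw plate data are publicly available, so the package ships a
generator that emulates the study conditions with known ground truth:

* **blank model**: Gaussian read noise (SD 20 ADU) on a constant offset
  (500 ADU), rounded and clipped to 14 bits. This is the simplest model
  that exercises the empirical cutoff rule; a Poisson–Gaussian option
  exists behind `poisson_noise = TRUE`. No evanescent-field optics or
  camera gain modelling is attempted;
* **spots**: symmetric 2D Gaussians, σ = 1.5 px, at uniform sub-pixel
  positions; peak amplitudes log-normal with mean 4000, SD 2000 ADU. The
  true aggregate-intensity distribution is unpublished; these are
  explicit placeholders exposed in `imaging_params()`;
* **plates**: per-image true spot counts are Poisson with mean
  `spots_per_fM × concentration`; the default rate 0.016
  spots/image/fM places the limit of detection in the low-femtomolar
  range, as in the study, with the standard series as the 1:5 ladder
  0.64 fM – 10 pM and blanks in 24-fold replication;
* **cohort**: per-subject true concentrations log-normal per group
  (26 disease vs 31 control subjects), common log-SD 1.6, control
  geometric mean 40 fM, and a group shift of $0.754\sigma$ chosen so the
  analytic normal-model AUC $\Phi(\Delta/(\sigma\sqrt 2))$ equals the
  published discrimination level of about 0.70; technical replicates are
  jittered at CV 18.7 %, the published mean fecal intra-assay CV. The
  resulting concentrations span roughly 1.6 fM–3 pM, matching the
  reported cohort range. Demographics (consistency scores, age, sex) are
  drawn from the reported group summaries, independent of concentration,
  so covariate correlations are null by construction.

What passing tests on these data show — and what they do not: the suites
demonstrate that the algorithms are correct (cutoff equals an exhaustive
oracle, AUC equals the U identity, slope recovery within 10 % of a
Monte-Carlo generative rate, type-I error of the null cohort pipeline at
its nominal level). They do not validate the noise model against a real
camera, the spot model against real aggregates, or the log-normal cohort
against real patients; published plate-level values (mean CVs,
selectivity percentages, depletion percentages, recovery, inter-assay ρ,
the measured 1.68 fM LoD) depend on unreleased raw data and are covered
only as formula identities.

## Problem sizes and numerical choices

The test suites run on scaled geometries — typically 120 × 120 px frames
with 4 images per well, and 200–1000 simulated wells or cohorts per
property — sizes at which every Monte-Carlo tolerance quoted above is
comfortably resolved while the full suite completes in a couple of
minutes. Full-size 1000 × 1000 × 25 generation is exercised where the
quantity demands it (the pooled-blank cutoff check uses 24 full frames,
$2.4\times10^7$ pixels). Degenerate inputs have defined behaviour
throughout: constant blanks yield the constant as cutoff; zero-spread
data are flagged rather than tested; all-identical cohort concentrations
yield AUC 0.5 with a degeneracy flag; empty groups, missing blank wells,
and all-excluded calibration points abort with explicit errors rather
than propagate silently.

## Known limitations

* The generator's spot-amplitude and noise parameters are placeholders
  where the acquisition hardware is unpublished; conclusions about real
  plates require re-estimating them.
* QC thresholds were chosen against the generator's corruption modes;
  real artifact taxonomies (dust, smears, illumination gradients) are
  broader.
* The linear-range rule and the pooling scope of the cutoff are stated
  conventions for an unpublished procedure, not reconstructions of the
  original software's behaviour.
* No covariate-adjusted modelling is provided: the cohorts the package
  targets are small proof-of-concept designs, and age/sex matching is a
  study-design question, not an analysis option.
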