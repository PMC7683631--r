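---
title: "Quantitative PET uptake corrections and mutation-separation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET uptake corrections and mutation-separation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcorr)
```

## The problem

Standardized uptake values (SUV) measured on FDG-PET images of small liver
lesions are biased by two effects that have nothing to do with tumor
biology. First, the scanner's limited resolution smears activity out of
small objects (the partial volume effect, PVE): a lesion near the
resolution limit can lose half of its apparent uptake. Second, SUV keeps
rising with the time between tracer injection and scan, so scans acquired
at 40 and at 200 minutes post-injection are not comparable. In an
interventional setting (PET-guided biopsies), uptake times are dictated by
procedure logistics and vary widely, making the second effect dominant in
exactly the cohorts where lesion-level molecular ground truth is
available. `petcorr` implements the full correction chain and the
downstream statistics used to ask whether corrected uptake separates KRAS
missense-mutant from wild-type liver metastases.

## Recovery coefficients and the cold-wall problem

PVE correction rests on recovery coefficients (RC) measured on an
image-quality phantom: hot spheres of known inner diameter (10-37 mm)
filled at a sphere-to-background activity ratio (here 2.19:1, 9.284 vs
4.240 kBq/mL, approximating the patient tumor-to-liver ratio) in a warm
background. The NEMA contrast form is used throughout:

$$RC = \frac{C/C_B - 1}{a_H/a_B - 1},$$

where \(C\) is the mean, peak (mean over a centred ~1 mL VOI) or max
statistic over the sphere VOI, \(C_B\) the background mean, and
\(a_H, a_B\) the true activity concentrations.

Physical phantom spheres have ~1 mm plastic walls that carry no activity;
lesions do not. `petcorr` models the blurred image of a walled sphere
analytically — a uniform ball convolved with an isotropic Gaussian PSF has
a radially symmetric closed form (`ball_gaussian_value()`), and the walled
sphere is a superposition of three such terms — and corrects each measured
RC by the ratio of the simulated statistic for the wall-free sphere to the
walled one (`cold_wall_factor()`).

Two numerical choices here deserve note:

* **Form of the wall ratio.** Taking the ratio on the contrast-form RCs
  yields 29-36% corrections for a 1 mL sphere (mean statistic, FWHM
  6-8 mm), far larger than the ~10% this correction is known to be.
  Taking it on the absolute blurred VOI statistic values yields ~10% at
  1 mL, under 5% above 10 mL, and a vanishing correction for the max
  statistic of large spheres. `petcorr` uses the absolute-value ratio.
  The max-statistic correction at 1 mL is FWHM- and form-dependent
  (roughly 5-19% across plausible choices) and should not be
  over-interpreted.
* **PSF width.** The PSF FWHM of a reconstructed image is rarely
  published. The default is 6.5 mm isotropic, consistent with a 6.4 mm
  post-filter; it is a config parameter (`psf_fwhm_mm`) and every wall
  correction magnitude quoted here moves with it. The model
  sphere-to-background ratio defaults to 2.26, midway between the phantom
  fill ratio and the observed patient tumor-to-liver ratio.

`build_rc_curve()` turns measured per-sphere RCs into a continuous curve:
cold-wall-corrected knots, monotone piecewise-cubic interpolation in
(log10 volume, RC) — chosen because it preserves the monotone trend
without overshoot — and, beyond the measured range on both sides,
the analytic model RC shape rescaled to pass through the terminal knot.
Extending the lower tail by the model (rather than clamping) mirrors the
model-based extension used for lesions larger than the biggest sphere;
observed lesions (0.2 mL) are smaller than the smallest sphere (0.52 mL),
so the lower tail is exercised in practice.

## The digital phantom

`render_phantom()` voxelizes spheres (with cold walls) and a zero-activity
lung-insert cylinder into a warm grid with partial-volume-accurate
boundary subsampling, blurs with the Gaussian PSF by FFT, and optionally
adds zero-mean Gaussian voxel noise (a post-reconstruction surrogate — not
Poisson projection noise — sufficient to reproduce the positive bias of
the max statistic). `measure_rc()` then reproduces the RC measurement:
sphere VOIs matching the inner diameters at the known centres, and twelve
37 mm background ROIs placed on the sphere ring rotated 30° off the
spheres and offset ±30 mm axially — a documented stand-in for the
standard's denser background layout, adequate for synthetic testing.

What a green phantom test establishes: the measurement chain
(voxelization → blur → VOI statistics → contrast form) agrees with the
analytic model to ~2% and noise behaves as expected. What it does not
establish: anything about scatter, attenuation, reconstruction artifacts
or segmentation of real images, which are outside scope. Note also that
the voxel-centre VOI mean has an \(O(\text{voxel}/R)\) negative bias on
*unblurred* images (~5% at 2 mm voxels for a 28 mm sphere); blurring
smooths the field and removes most of it.

## Lesion corrections

For each lesion with volume \(V\), the statistic-matched RC is looked up
from the curve, and the partial-volume corrected SUV is

$$\mathrm{SUV}^{PVEC} = \frac{\mathrm{SUV}}{RC} -
  \mathrm{SUV}_B\left(\frac{1}{RC} - 1\right),$$

the exact inverse of the forward model
\(\text{measured} = RC\cdot\text{true} + (1-RC)\cdot\text{background}\),
with the local background taken from a doughnut ROI around the lesion.
Negative corrected values (background exceeding signal at small RC) are
flagged, never clipped. Lesions smaller than the 1.0 mL peak VOI have no
genuine peak; the mean is substituted and flagged (`peak_fallback()`).

The tumor-to-blood ratio \(\mathrm{SUR} = \mathrm{SUV}/\mathrm{SUV}_{blood}\)
cancels multiplicative calibration errors (injected activity, weight,
scanner calibration) and is the basis of the uptake-time correction to
the reference time \(T_0 = 60\) min:

$$\mathrm{SUR}_0 = \frac{T_0}{T}(\mathrm{SUR}_T - V_r) + V_r
  \approx \mathrm{SUR}_T\frac{T_0}{T}, \qquad
  \mathrm{SUV}_0 = \mathrm{SUV}_T\frac{\mathrm{SUR}_0}{\mathrm{SUR}_T}
  \left(\frac{T_0}{T}\right)^{-b}
  \approx \mathrm{SUV}_T\left(\frac{T_0}{T}\right)^{1-b},$$

with \(V_r = 0.53\) and \(b = 0.313\). Both forms are implemented; the
default is the approximate form, the one stated to have been applied in
the source analysis. The two forms are *not* generally within a few
percent of each other: they differ by \(V_r(T_0/T - 1)\), which is ~12%
of the exact value at \(\mathrm{SUR}_T = 4, T = 120\) min and grows toward
the long-uptake end of the observed 40-206 min range. The exact SUV form
consumes the exact SUR form for self-consistency.

`correct_cohort()` locks the pipeline order: RC lookup → PVEC per
statistic → ratios from PVE-corrected values → time correction last.
Permuting time correction before PVEC changes the result; the order is
regression-tested.

## Molecular annotations

`parse_kras()` recognizes the three report forms (missense
`G12D (c.35G > A) exon 2`, whole-gene amplification with optional fold
change and panel suffix, and empty/wild type), tolerating the whitespace
and punctuation variation the reports themselves show; anything else is a
loud parse error. Amplification cases are grouped with wild type in the
primary labelling policy (`amp_with_wt`; missense mutations and
amplification are mutually exclusive and only missense reliably predicts
anti-EGFR resistance) and with the mutants under `amp_with_mut` for the
supplementary analysis. The shipped 37-patient fixture reproduces the
published composition (15 missense — 8 codon 12, 4 codon 13, 2 codon 61,
1 codon 146 — and 3 amplifications). The source also reports the missense
share as 37.8% although 15/37 = 40.5%; the fixture keeps n = 15 and the
discrepancy is simply noted.

## Separation statistics

`build_results_grid()` evaluates each metric family (raw SUV, PVEC SUV,
PVEC tumor-to-liver ratio, PVEC+time SUV, time-corrected SUR, PVEC+time
SUR) × statistic × segmentation tag: two-sided t tests (pooled-variance
by default — the conventional reading of "Student's t" — with Welch
alongside, since published rounded p values cannot distinguish them),
Wilcoxon rank-sum with continuity and tie correction (normal
approximation), the empirical ROC with Mann-Whitney AUC (ties count one
half), and a univariate logistic fit. "Optimal cutoff" is defined as the
threshold maximizing the Youden index on the empirical ROC (ties broken
toward the smaller threshold, favouring sensitivity); the probability-0.5
crossing of the logistic curve is reported alongside. No multiple-testing
correction is applied, matching the source analysis. Complete separation
flags the logistic fit as non-convergent while the ROC cutoff is still
reported.

## Synthetic cohorts

Real per-lesion data are not deposited, so the generators stand in for
them in two modes:

* **Summary-matched** (`generate_summary_matched()`): draws final
  corrected metric values per group from truncated normal distributions
  (lower bound 0 — uptake metrics are positive; the truncated mass is
  ~2.5% at the most affected moments) with the published group means/SDs,
  at the 36 wild-type-grouped / 24 mutant split implied by the published
  sensitivity/specificity denominators (0.72 = 26/36, 0.88 = 21/24). This
  reproduces table-scale statistics but contains no correction structure.
* **Forward-model** (`generate_forward_model()`): samples true,
  correction-free uptake per group, then applies the measurement physics
  forward (power-law uptake growth to scan time, RC attenuation with
  background fill-in, optional 5% multiplicative metric noise, max/mean
  coupling drawn from [1.3, 1.7] consistent with the published group
  moments, peak halfway between). Running `correct_cohort()` on this
  cohort recovers the true uptake exactly in the noise-free case — the
  round-trip property that validates the correction algebra end to end.

Distribution-family choices the source does not constrain (lognormal
uptake times and volumes — both quantities are positive and
right-skewed; normal blood/liver/background SUV truncated above 0.5) are
fixed once here and exposed in `cohort_params()`. Uptake times use mean
83.8, SD 34, range [40.7, 205.7] min; blood 2.2 ± 0.6; liver 2.7 ± 0.6;
local background 2.4 ± 0.7; volumes mean 5.7 mL (between the two
segmentations' 5.3 and 6.1 mL), range [0.2, 43] mL. A green
summary-matched test establishes that the statistics module reproduces
the published discrimination given the published moments; it cannot
validate the corrections themselves (the forward model does that), and
neither mode models per-patient lesion clustering — lesions are treated
as independent, as in the source analysis.

## Limitations

* All wall-correction magnitudes depend on the assumed PSF FWHM; only
  their qualitative structure (size dependence, statistic ordering) is
  testable without the scanner's true PSF.
* The phantom noise model is Gaussian in image space; absolute noise
  levels are not calibrated to any scanner.
* The 36/24 lesion split is an inference from published fractions, not a
  stated count; it is configurable.
* The package analyzes tabular lesion metrics; it does not segment
  images, parse DICOM, or model reconstruction.
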