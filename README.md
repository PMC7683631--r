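# petcorr

Quantitative correction chain for FDG-PET uptake metrics of liver
lesions, with the downstream statistics that ask whether corrected uptake
separates KRAS missense-mutant from wild-type metastases.

Small lesions lose apparent uptake to the scanner's finite resolution
(partial volume effect), and SUV keeps growing with the injection-to-scan
time, which varies widely in interventional (biopsy-guidance) PET. The
package implements:

* an analytic recovery-coefficient (RC) model — uniform spheres in warm
  background under isotropic Gaussian blur, with **cold-wall correction**
  factors for the inactive plastic walls of phantom spheres
  (`ball_gaussian_value()`, `model_rc()`, `cold_wall_factor()`,
  `build_rc_curve()`);
* a **digital image-quality phantom** (six spheres, 10-37 mm, 2.19:1
  sphere-to-background, cold lung insert) with measured-RC extraction in
  the NEMA contrast form `RC = (C/C_B - 1) / (a_H/a_B - 1)`
  (`render_phantom()`, `measure_rc()`);
* lesion-level **partial-volume correction**
  `SUV_PVEC = SUV/RC - SUV_B (1/RC - 1)`, tumor-to-liver ratio, and the
  tumor-to-blood ratio `SUR = SUV / SUV_blood` with **uptake-time
  normalization** to T0 = 60 min,
  `SUR_0 = (T0/T)(SUR_T - V_r) + V_r ≈ SUR_T T0/T` and
  `SUV_0 ≈ SUV_T (T0/T)^(1-b)` with V_r = 0.53, b = 0.313
  (`pvec()`, `sur()`, `time_correct_sur()`, `correct_cohort()`);
* **KRAS annotation parsing** (missense / whole-gene amplification / wild
  type) and the two amplification grouping policies (`parse_kras()`,
  `kras_labels()`);
* **separation statistics**: pooled and Welch t tests (raw and from
  summary moments), Wilcoxon rank-sum with continuity correction,
  empirical ROC/AUC, logistic regression with Youden-optimal cutoff,
  assembled into a metric-by-correction results grid
  (`build_results_grid()`);
* **synthetic cohorts** in summary-matched and forward-model (ground
  truth, exactly invertible) modes (`generate_summary_matched()`,
  `generate_forward_model()`).

## Worked example

Build RC curves from a noiseless digital phantom, correct a synthetic
forward-model cohort, and test the separation:

```r
library(petcorr)

cfg <- pipeline_config(psf_fwhm_mm = 6.5, seed = 1)
ph <- run_phantom(cfg)          # renders the phantom, measures RCs
ph$curves$mean$table[, c("inner_diameter_mm", "rc_measured",
                         "wall_factor", "rc_final")]
#>  inner_diameter_mm rc_measured wall_factor  rc_final
#>                 10   0.2629382    1.123998 0.2955420
#>                 13   0.3969521    1.096280 0.4351707
#>                 17   0.5159622    1.072830 0.5535397
#>                 22   0.6190482    1.055458 0.6533796
#>                 28   0.6919911    1.043008 0.7217524
#>                 37   0.7659167    1.032131 0.7905261
```

The measured mean-statistic RC for the 10 mm sphere recovers only ~26%
of the true contrast; the cold-wall factor raises it by ~12% (the wall
keeps warm background away from the sphere in the phantom, a
configuration real lesions never have) and fades below 4% for the
largest sphere.

```r
curves <- ph$curves
cohort <- generate_forward_model(rc_curves = curves, noise_sd = 0.05,
                                 seed = 2)
corrected <- correct_cohort(cohort, curves)
grid <- build_results_grid(corrected,
                           families = c("suv", "suv_pvec",
                                        "suv_pvec_time"),
                           statistics = "max")
grid[, c("family", "t_p", "auc", "cutoff", "sensitivity", "specificity")]
#>         family         t_p       auc    cutoff sensitivity specificity
#>            suv 0.022561199 0.6597222 13.774396   0.5833333   0.7500000
#>       suv_pvec 0.011447195 0.6770833 12.891093   0.7083333   0.6111111
#>  suv_pvec_time 0.002857418 0.7326389  9.244005   0.7916667   0.6388889
```

Each correction stage sharpens the separation of the two simulated
groups on SUV_MAX (p falls from 0.023 to 0.003, AUC rises from 0.66 to
0.73): the partial-volume and uptake-time corrections remove variance
that is instrumental, not biological, and the forward-model generator
guarantees a ground truth the chain must recover.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline reconstruction from scratch: it simulates the
threshold-segmentation arm of the fully corrected SUR_MAX metric from the
published group moments (36 wild-type-grouped vs 24 mutant lesions),
averages the empirical ROC AUC over 1000 seeded replicates, and writes
the result as JSON.

## Layout

* `R/` — RC model, phantom, corrections, annotation parsing, statistics,
  synthetic cohorts, pipeline workflows
* `inst/extdata/` — transcribed annotation and group-moment fixtures
* `vignettes/pet-uptake-corrections.Rmd` — model assumptions, parameter
  choices, numerical decisions, limitations
* `tests/testthat/` — unit, property and acceptance suites (grid
  convolution, enumeration and direct-ML oracles in
  `helper-oracles.R`)
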