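# Lesion-level metric corrections: partial-volume correction, tumor-to-liver
# and tumor-to-blood ratios, uptake-time normalization to T0 = 60 min.

#' Uptake-time correction parameters
#'
#' Parameters of the tumor-to-blood SUR uptake-time normalization: the
#' standard reference time `t0_min`, the apparent volume of distribution
#' `vr` (the asymptotic blood-normalized uptake offset), and the power-law
#' exponent `b` of the blood SUV decay. Defaults are the published values
#' T0 = 60 min, V_r = 0.53, b = 0.313.
#'
#' @param t0_min Reference uptake time in minutes (> 0).
#' @param vr Apparent volume of distribution, dimensionless (>= 0).
#' @param b Blood-decay power-law exponent, in `[0, 1)`.
#' @return An object of class `uptake_params`.
#' @export
uptake_params <- function(t0_min = 60, vr = 0.53, b = 0.313) {
  stopifnot(is.numeric(t0_min), t0_min > 0, is.numeric(vr), vr >= 0,
            is.numeric(b), b >= 0, b < 1)
  structure(list(t0_min = t0_min, vr = vr, b = b), class = "uptake_params")
}

#' Partial-volume correction of an uptake statistic
#'
#' Inverts the forward partial-volume attenuation
#' `measured = rc * true + (1 - rc) * background`:
#' \deqn{SUV^{PVEC} = SUV / RC - SUV_B (1/RC - 1)}
#' The same formula serves the mean, peak and max statistics with the
#' statistic-matched recovery coefficient.
#'
#' @param suv Measured SUV statistic (vectorized).
#' @param rc Recovery coefficient(s), positive.
#' @param suv_bg Local background SUV around the lesion (the doughnut-ROI
#'   mean).
#' @return Corrected SUV. Non-positive results (background exceeding the
#'   lesion signal at small `rc`) are returned as-is with a warning, never
#'   clipped.
#' @export
#' @examples
#' pvec(6.0, 0.8, 2.4) # 6/0.8 - 2.4 * 0.25 = 6.9
pvec <- function(suv, rc, suv_bg) {
  if (any(!is.finite(rc)) || any(rc <= 0)) {
    stop("'rc' must be positive and finite", call. = FALSE)
  }
  out <- suv / rc - suv_bg * (1 / rc - 1)
  bad <- is.finite(out) & out <= 0 & suv > 0
  if (any(bad)) {
    warning(sum(bad), " partial-volume corrected value(s) <= 0: ",
            "background exceeds lesion signal", call. = FALSE)
  }
  out
}

#' Tumor-to-liver ratio
#'
#' Ratio of the (partial-volume corrected) lesion SUV to the mean normal
#' liver SUV.
#'
#' @param suv Lesion SUV (typically PVE-corrected).
#' @param suv_liver Mean normal-liver SUV, positive.
#' @return Dimensionless ratio.
#' @export
suvtlr <- function(suv, suv_liver) {
  if (any(!is.finite(suv_liver)) || any(suv_liver <= 0)) {
    stop("'suv_liver' must be positive", call. = FALSE)
  }
  suv / suv_liver
}

#' Tumor-to-blood standard uptake ratio (SUR)
#'
#' Ratio of the lesion SUV to the mean blood SUV (descending aorta). SUR is
#' invariant under any common multiplicative SUV miscalibration (injected
#' activity, body weight, scanner calibration), which is its rationale.
#'
#' @param suv Lesion SUV statistic.
#' @param suv_blood Mean blood SUV, positive.
#' @return Dimensionless ratio.
#' @export
sur <- function(suv, suv_blood) {
  if (any(!is.finite(suv_blood)) || any(suv_blood <= 0)) {
    stop("'suv_blood' must be positive", call. = FALSE)
  }
  suv / suv_blood
}

#' Normalize a SUR to the standard uptake time
#'
#' Scales a tumor-to-blood ratio measured at uptake time `t_min` to the
#' reference time T0:
#' \deqn{SUR_0 = (T_0/T)(SUR_T - V_r) + V_r \approx SUR_T \, T_0/T}
#' `mode = "exact"` applies the affine form (with fixed point at `V_r`);
#' `mode = "approx"` the ratio form.
#'
#' @param sur_t SUR at the actual uptake time (vectorized).
#' @param t_min Uptake time in minutes, positive.
#' @param params An [uptake_params()].
#' @param mode `"approx"` (default) or `"exact"`.
#' @return SUR referenced to `params$t0_min`.
#' @export
time_correct_sur <- function(sur_t, t_min, params = uptake_params(),
                             mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "uptake_params"))
  if (any(!is.finite(t_min)) || any(t_min <= 0)) {
    stop("'t_min' must be positive", call. = FALSE)
  }
  ratio <- params$t0_min / t_min
  if (mode == "exact") {
    ratio * (sur_t - params$vr) + params$vr
  } else {
    sur_t * ratio
  }
}

#' Normalize a SUV to the standard uptake time
#'
#' Scales a lesion SUV measured at uptake time `t_min` to the reference
#' time T0:
#' \deqn{SUV_0 = SUV_T \frac{SUR_0}{SUR_T}\left(\frac{T_0}{T}\right)^{-b}
#'   \approx SUV_T \left(\frac{T_0}{T}\right)^{1-b}}
#' The exact form needs the lesion's SUR at scan time (computed with the
#' exact SUR correction for self-consistency); the approximate power-law
#' form needs only the time.
#'
#' @param suv_t SUV at the actual uptake time (vectorized).
#' @param t_min Uptake time in minutes, positive.
#' @param params An [uptake_params()].
#' @param mode `"approx"` (default) or `"exact"`.
#' @param sur_t SUR at scan time; required (positive) for `mode = "exact"`.
#' @return SUV referenced to `params$t0_min`.
#' @export
time_correct_suv <- function(suv_t, t_min, params = uptake_params(),
                             mode = c("approx", "exact"), sur_t = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "uptake_params"))
  if (any(!is.finite(t_min)) || any(t_min <= 0)) {
    stop("'t_min' must be positive", call. = FALSE)
  }
  ratio <- params$t0_min / t_min
  if (mode == "exact") {
    if (is.null(sur_t)) {
      stop("exact SUV time correction requires 'sur_t'", call. = FALSE)
    }
    if (any(!is.finite(sur_t)) || any(sur_t <= 0)) {
      stop("'sur_t' must be positive in exact mode", call. = FALSE)
    }
    sur_0 <- time_correct_sur(sur_t, t_min, params, mode = "exact")
    suv_t * (sur_0 / sur_t) * ratio^(-params$b)
  } else {
    suv_t * ratio^(1 - params$b)
  }
}

#' Peak-statistic fallback for small lesions
#'
#' When a lesion is smaller than the peak VOI the peak statistic is not
#' measurable and the mean is substituted, with a flag.
#'
#' @param lesions Lesion data frame with columns `volume_mL`, `suv_mean`,
#'   `suv_peak`.
#' @param peak_voi_ml Peak VOI volume in mL (default 1.0).
#' @return The data frame with `suv_peak` substituted where
#'   `volume_mL < peak_voi_ml` and a logical `peak_substituted` column.
#' @export
peak_fallback <- function(lesions, peak_voi_ml = 1.0) {
  stopifnot(is.data.frame(lesions),
            all(c("volume_mL", "suv_mean", "suv_peak") %in% names(lesions)))
  sub <- lesions$volume_mL < peak_voi_ml
  lesions$suv_peak[sub] <- lesions$suv_mean[sub]
  lesions$peak_substituted <- sub
  lesions
}

lesion_required_cols <- c("volume_mL", "suv_mean", "suv_peak", "suv_max",
                          "suv_bg_local", "suv_liver_mean", "suv_blood_mean",
                          "uptake_time_min")

#' Apply the full correction chain to a lesion cohort
#'
#' Enforces the pipeline order: recovery-coefficient lookup by lesion
#' volume, partial-volume correction per statistic, tumor-to-liver and
#' tumor-to-blood ratios computed from the PVE-corrected values, uptake-time
#' correction last. Emits all six metric families per statistic:
#' raw `suv`, `suv_pvec`, `suvtlr_pvec`, `suv_pvec_time`, `sur_time`
#' (time-corrected SUR of the uncorrected SUV) and `sur_pvec_time`.
#'
#' @param lesions Lesion data frame; required columns `volume_mL`,
#'   `suv_mean`, `suv_peak`, `suv_max`, `suv_bg_local`, `suv_liver_mean`,
#'   `suv_blood_mean`, `uptake_time_min` (any identifier columns are
#'   carried through).
#' @param rc_curves Named list of `rc_curve` objects with elements `mean`,
#'   `peak`, `max` (see [build_rc_curve()]).
#' @param params An [uptake_params()].
#' @param mode Time-correction mode, `"approx"` (default) or `"exact"`.
#' @param peak_voi_ml Peak VOI volume for [peak_fallback()]; `NULL` skips
#'   the fallback.
#' @param apply_pvec,apply_time Logical switches; with both `FALSE` (or
#'   `rc = 1` and `T = T0`) all corrected variants collapse to the raw
#'   metrics and ratios.
#' @return The input data frame extended with columns
#'   `rc_<stat>`, `suv_pvec_<stat>`, `suvtlr_pvec_<stat>`,
#'   `suv_pvec_time_<stat>`, `sur_time_<stat>`, `sur_pvec_time_<stat>` for
#'   each statistic, plus bookkeeping flags.
#' @export
correct_cohort <- function(lesions, rc_curves, params = uptake_params(),
                           mode = c("approx", "exact"), peak_voi_ml = 1.0,
                           apply_pvec = TRUE, apply_time = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(lesions))
  missing_cols <- setdiff(lesion_required_cols, names(lesions))
  if (length(missing_cols)) {
    stop("lesion table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (apply_pvec) {
    stopifnot(is.list(rc_curves),
              all(c("mean", "peak", "max") %in% names(rc_curves)))
  }
  if (any(lesions$volume_mL <= 0) || any(lesions$uptake_time_min <= 0)) {
    stop("volumes and uptake times must be positive", call. = FALSE)
  }
  out <- if (!is.null(peak_voi_ml)) peak_fallback(lesions, peak_voi_ml)
         else lesions
  t_min <- out$uptake_time_min
  for (stat in c("mean", "peak", "max")) {
    raw <- out[[paste0("suv_", stat)]]
    rc <- if (apply_pvec) {
      predict(rc_curves[[stat]], out$volume_mL)
    } else {
      rep(1, nrow(out))
    }
    out[[paste0("rc_", stat)]] <- rc
    sp <- pvec(raw, rc, out$suv_bg_local)
    out[[paste0("suv_pvec_", stat)]] <- sp
    out[[paste0("suvtlr_pvec_", stat)]] <- suvtlr(sp, out$suv_liver_mean)
    sur_raw <- sur(raw, out$suv_blood_mean)
    sur_pvec <- sur(sp, out$suv_blood_mean)
    if (apply_time) {
      out[[paste0("suv_pvec_time_", stat)]] <-
        time_correct_suv(sp, t_min, params, mode, sur_t = sur_pvec)
      out[[paste0("sur_time_", stat)]] <-
        time_correct_sur(sur_raw, t_min, params, mode)
      out[[paste0("sur_pvec_time_", stat)]] <-
        time_correct_sur(sur_pvec, t_min, params, mode)
    } else {
      out[[paste0("suv_pvec_time_", stat)]] <- sp
      out[[paste0("sur_time_", stat)]] <- sur_raw
      out[[paste0("sur_pvec_time_", stat)]] <- sur_pvec
    }
  }
  out$pvec_implausible <- Reduce(`|`, lapply(c("mean", "peak", "max"),
    function(s) out[[paste0("suv_pvec_", s)]] <= 0))
  out
}

#' Correct a single lesion record
#'
#' Single-row convenience wrapper around [correct_cohort()].
#'
#' @inheritParams correct_cohort
#' @param lesion One-row data frame (or coercible list) of lesion metrics.
#' @return One-row corrected data frame.
#' @export
correct_lesion <- function(lesion, rc_curves, params = uptake_params(),
                           mode = c("approx", "exact"), peak_voi_ml = 1.0,
                           apply_pvec = TRUE, apply_time = TRUE) {
  if (!is.data.frame(lesion)) lesion <- as.data.frame(lesion)
  stopifnot(nrow(lesion) == 1L)
  correct_cohort(lesion, rc_curves, params, mode, peak_voi_ml,
                 apply_pvec, apply_time)
}
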