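# Synthetic-cohort generation: summary-matched draws from published group
# moments, and a forward lesion model whose corrections are exactly
# invertible, plus the transcribed annotation and moment fixtures.

#' Published per-group metric moments
#'
#' The transcribed table of group means and standard deviations (wild-type
#' grouped vs missense mutant) for every metric family, statistic and
#' segmentation tag, shipped with the package as a CSV fixture.
#'
#' @return Data frame with columns `family`, `segmentation`, `statistic`,
#'   `mean_wt`, `sd_wt`, `mean_mut`, `sd_mut`.
#' @export
table3_moments <- function() {
  utils::read.csv(system.file("extdata", "table3_moments.csv",
                              package = "petcorr"),
                  stringsAsFactors = FALSE)
}

#' Transcribed molecular-pathology annotation fixture
#'
#' The 18 verbatim mutation / amplification annotation strings of the
#' 37-patient cohort (15 missense, 3 whole-gene amplification) plus the 19
#' wild-type patients as empty annotations.
#'
#' @return Data frame with columns `case_id` and `annotation` (37 rows).
#' @export
table2_fixture <- function() {
  tab <- utils::read.csv(system.file("extdata", "table2_annotations.csv",
                                     package = "petcorr"),
                         stringsAsFactors = FALSE,
                         colClasses = c("integer", "character"))
  tab$annotation[is.na(tab$annotation)] <- ""
  tab
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# lognormal parameterized by its arithmetic mean/sd, truncated to a range
rlnorm_match <- function(n, mean, sd, lower = 0, upper = Inf) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  out <- stats::qlnorm(
    stats::runif(n,
                 stats::plnorm(lower, meanlog, sqrt(sdlog2)),
                 stats::plnorm(upper, meanlog, sqrt(sdlog2))),
    meanlog, sqrt(sdlog2))
  out
}

#' Synthetic-cohort parameters
#'
#' The stated world of the emulated study: 36 wild-type-grouped and 24
#' mutant lesions; uptake times lognormal with mean 83.8 min and SD 34 min
#' truncated to the observed 40.7-205.7 min range; blood SUV normal
#' 2.2 +- 0.6 (truncated above 0.5); normal-liver SUV 2.7 +- 0.6; local
#' lesion background SUV 2.4 +- 0.7; lesion volumes lognormal with mean
#' 5.7 mL and SD 7.7 mL truncated to the observed 0.2-43 mL range; true
#' (fully corrected) lesion SUV moments per group for the forward model.
#'
#' @param n_wt,n_mut Group sizes (wild-type-grouped, mutant).
#' @param uptake_mean_min,uptake_sd_min,uptake_range_min Uptake-time
#'   distribution (lognormal, truncated).
#' @param blood_mean,blood_sd Blood SUV distribution (normal, > 0.5).
#' @param liver_mean,liver_sd Normal-liver SUV distribution.
#' @param bg_mean,bg_sd Local lesion-background SUV distribution.
#' @param volume_mean_ml,volume_sd_ml,volume_range_ml Lesion-volume
#'   distribution (lognormal, truncated).
#' @param true_suv0_wt,true_suv0_mut `c(mean, sd)` of the true
#'   (PVE-free, T0-referenced) mean-SUV per group used by the forward
#'   model; defaults follow the corrected mean-SUV group moments.
#' @param metric_noise_sd Relative multiplicative measurement noise on the
#'   forward-model metrics (default 0.05).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_wt = 36L, n_mut = 24L,
                          uptake_mean_min = 83.8, uptake_sd_min = 34,
                          uptake_range_min = c(40.7, 205.7),
                          blood_mean = 2.2, blood_sd = 0.6,
                          liver_mean = 2.7, liver_sd = 0.6,
                          bg_mean = 2.4, bg_sd = 0.7,
                          volume_mean_ml = 5.7, volume_sd_ml = 7.7,
                          volume_range_ml = c(0.2, 43.0),
                          true_suv0_wt = c(5.87, 2.14),
                          true_suv0_mut = c(7.22, 1.92),
                          metric_noise_sd = 0.05) {
  stopifnot(n_wt > 0, n_mut > 0, uptake_sd_min > 0, blood_sd > 0,
            liver_sd > 0, bg_sd > 0, volume_sd_ml > 0,
            metric_noise_sd >= 0,
            uptake_range_min[1] < uptake_range_min[2],
            volume_range_ml[1] < volume_range_ml[2])
  structure(as.list(environment()), class = "cohort_params")
}

#' Summary-matched synthetic cohort
#'
#' Draws final corrected metric values directly from per-group truncated
#' normal distributions with the published moments for one metric family
#' and segmentation, reproducing downstream table-scale statistics without
#' any raw data. Deterministic per seed.
#'
#' @param params A [cohort_params()] (group sizes are taken from it).
#' @param family Metric family, one of
#'   `"suv"`, `"suv_pvec"`, `"suvtlr_pvec"`, `"suv_pvec_time"`,
#'   `"sur_time"`, `"sur_pvec_time"`.
#' @param segmentation `"mim"` or `"hermes"`.
#' @param statistics Statistics to draw (default mean, peak, max).
#' @param moments Moment table (default [table3_moments()]); override to
#'   use custom moments.
#' @param lower Truncation lower bound for the metric draws (default 0;
#'   uptake metrics are positive).
#' @param seed Integer seed.
#' @return Data frame with columns `lesion_id`, `segmentation`, `label`
#'   (1 = mutant) and `<family>_<statistic>` value columns.
#' @export
generate_summary_matched <- function(params = cohort_params(),
                                     family = "sur_pvec_time",
                                     segmentation = "hermes",
                                     statistics = c("mean", "peak", "max"),
                                     moments = table3_moments(),
                                     lower = 0, seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  n0 <- params$n_wt
  n1 <- params$n_mut
  out <- data.frame(lesion_id = seq_len(n0 + n1),
                    segmentation = segmentation,
                    label = rep(c(0L, 1L), c(n0, n1)))
  for (stat in statistics) {
    row <- moments[moments$family == family &
                     moments$segmentation == segmentation &
                     moments$statistic == stat, ]
    if (nrow(row) != 1L) {
      stop("no unique moment row for ", family, "/", segmentation, "/",
           stat, call. = FALSE)
    }
    if (row$sd_wt <= 0 || row$sd_mut <= 0) {
      stop("non-positive SD in moment table", call. = FALSE)
    }
    out[[paste0(family, "_", stat)]] <- c(
      rtruncnorm(n0, row$mean_wt, row$sd_wt, lower = lower),
      rtruncnorm(n1, row$mean_mut, row$sd_mut, lower = lower)
    )
  }
  out
}

#' Forward-model synthetic cohort with ground truth
#'
#' Samples true (PVE-free, T0-referenced) lesion uptake per group, then
#' runs the measurement process forward: the uptake grows to scan time by
#' the power law `true_T = SUV_0 (T/T0)^(1-b)`, the scanner attenuates it
#' by the volume-dependent recovery coefficient with background fill-in
#' (`measured = rc * true_T + (1 - rc) * background`), and optional
#' multiplicative Gaussian noise is applied. Peak and max are coupled to
#' the mean by a max/mean factor drawn uniformly from `[1.3, 1.7]` (peak
#' halfway between). Running [correct_cohort()] on the result recovers
#' `SUV_0` exactly in the noise-free case.
#'
#' @param params A [cohort_params()].
#' @param rc_curves Named list of `rc_curve` objects (`mean`, `peak`,
#'   `max`).
#' @param uptake A [uptake_params()].
#' @param noise_sd Relative metric noise; default taken from `params`.
#' @param seed Integer seed.
#' @return Data frame in the raw lesion schema of [correct_cohort()] plus
#'   ground-truth columns `true_suv0_<stat>`, `true_rc_<stat>` and
#'   `label`.
#' @export
generate_forward_model <- function(params = cohort_params(), rc_curves,
                                   uptake = uptake_params(),
                                   noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(params, "cohort_params"),
            inherits(uptake, "uptake_params"),
            all(c("mean", "peak", "max") %in% names(rc_curves)))
  if (is.null(noise_sd)) noise_sd <- params$metric_noise_sd
  set.seed(as.integer(seed))
  n0 <- params$n_wt
  n1 <- params$n_mut
  n <- n0 + n1
  label <- rep(c(0L, 1L), c(n0, n1))

  suv0_mean <- c(
    rtruncnorm(n0, params$true_suv0_wt[1], params$true_suv0_wt[2],
               lower = 0.5),
    rtruncnorm(n1, params$true_suv0_mut[1], params$true_suv0_mut[2],
               lower = 0.5)
  )
  max_factor <- stats::runif(n, 1.3, 1.7)
  peak_factor <- 1 + (max_factor - 1) / 2
  suv0 <- cbind(mean = suv0_mean, peak = suv0_mean * peak_factor,
                max = suv0_mean * max_factor)

  volume <- rlnorm_match(n, params$volume_mean_ml, params$volume_sd_ml,
                         params$volume_range_ml[1],
                         params$volume_range_ml[2])
  t_min <- rlnorm_match(n, params$uptake_mean_min, params$uptake_sd_min,
                        params$uptake_range_min[1],
                        params$uptake_range_min[2])
  blood <- rtruncnorm(n, params$blood_mean, params$blood_sd, lower = 0.5)
  liver <- rtruncnorm(n, params$liver_mean, params$liver_sd, lower = 0.5)
  bg <- rtruncnorm(n, params$bg_mean, params$bg_sd, lower = 0.5)

  out <- data.frame(lesion_id = seq_len(n), label = label,
                    volume_mL = volume, suv_bg_local = bg,
                    suv_liver_mean = liver, suv_blood_mean = blood,
                    uptake_time_min = t_min)
  growth <- (t_min / uptake$t0_min)^(1 - uptake$b)
  for (stat in c("mean", "peak", "max")) {
    rc <- predict(rc_curves[[stat]], volume)
    true_t <- suv0[, stat] * growth
    measured <- rc * true_t + (1 - rc) * bg
    if (noise_sd > 0) {
      measured <- measured * (1 + stats::rnorm(n, 0, noise_sd))
    }
    out[[paste0("suv_", stat)]] <- measured
    out[[paste0("true_suv0_", stat)]] <- suv0[, stat]
    out[[paste0("true_rc_", stat)]] <- rc
  }
  out
}
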