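# Two-group separation statistics: t tests (pooled and Welch, raw and from
# summary statistics), Wilcoxon rank-sum with continuity correction,
# empirical ROC/AUC, univariate logistic regression with Youden-optimal
# cutoff, and the metric-by-correction results grid.

#' Two-sample t test
#'
#' Two-sided t test for a difference in means between the label-0 and
#' label-1 groups, in the classical pooled-variance form
#' (`variant = "student_pooled"`, the default) or the Welch unequal-variance
#' form. Degenerate input with zero variance in both groups and equal means
#' returns `p = 1` with a flag instead of failing.
#'
#' @param values0,values1 Numeric vectors for the two groups, each of
#'   length >= 2.
#' @param variant `"student_pooled"` (default) or `"welch"`.
#' @return List with `statistic`, `df`, `p_value`, `variant`, `degenerate`.
#' @export
t_test2 <- function(values0, values1,
                    variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(values0) >= 2L, length(values1) >= 2L,
            all(is.finite(values0)), all(is.finite(values1)))
  if (stats::var(values0) == 0 && stats::var(values1) == 0) {
    return(list(statistic = 0, df = NA_real_, p_value = 1,
                variant = variant, degenerate = TRUE))
  }
  ht <- stats::t.test(values1, values0,
                      var.equal = (variant == "student_pooled"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, variant = variant, degenerate = FALSE)
}

#' Two-sample t test from summary statistics
#'
#' Same statistic as [t_test2()] computed from group means, standard
#' deviations and sizes, enabling reconstructions from published
#' mean-and-SD tables without raw data. Equals `t_test2` on any raw sample
#' having exactly those moments.
#'
#' @param mean0,sd0,n0 Label-0 group mean, SD (> 0) and size (>= 2).
#' @param mean1,sd1,n1 Label-1 group moments.
#' @inheritParams t_test2
#' @return List with `statistic`, `df`, `p_value`, `variant`.
#' @export
t_test_from_summary <- function(mean0, sd0, n0, mean1, sd1, n1,
                                variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(sd0 > 0, sd1 > 0, n0 >= 2, n1 >= 2)
  if (variant == "student_pooled") {
    sp2 <- ((n0 - 1) * sd0^2 + (n1 - 1) * sd1^2) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- n0 + n1 - 2
  } else {
    v0 <- sd0^2 / n0
    v1 <- sd1^2 / n1
    se <- sqrt(v0 + v1)
    df <- (v0 + v1)^2 / (v0^2 / (n0 - 1) + v1^2 / (n1 - 1))
  }
  tval <- (mean1 - mean0) / se
  list(statistic = tval, df = df,
       p_value = 2 * stats::pt(-abs(tval), df), variant = variant)
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test using the
#' normal approximation with tie correction and, by default, a +-0.5
#' continuity correction. All-tied data returns `p = 1` with a flag.
#'
#' @param values0,values1 Group value vectors (length >= 2 each).
#' @param continuity Apply the continuity correction (default `TRUE`).
#' @return List with `statistic` (the rank-sum W for group 1 vs group 0),
#'   `p_value`, `degenerate`.
#' @export
wilcoxon_rank_sum <- function(values0, values1, continuity = TRUE) {
  stopifnot(length(values0) >= 2L, length(values1) >= 2L,
            all(is.finite(values0)), all(is.finite(values1)))
  if (length(unique(c(values0, values1))) == 1L) {
    return(list(statistic = length(values0) * length(values1) / 2,
                p_value = 1, degenerate = TRUE))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(values1, values0, exact = FALSE,
                       correct = continuity)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       degenerate = FALSE)
}

#' Empirical ROC curve and AUC
#'
#' Empirical receiver operating characteristic for separating the label-1
#' group (assumed to take larger values) from the label-0 group, sweeping
#' the decision threshold over all observed values. The AUC is computed via
#' the Mann-Whitney relation with ties counted one half.
#'
#' @param values0,values1 Group value vectors (non-empty).
#' @return Object of class `roc` with `auc` and a `curve` data frame
#'   (`threshold`, `fpr`, `tpr`), threshold meaning "positive if
#'   value >= threshold".
#' @export
roc <- function(values0, values1) {
  stopifnot(length(values0) >= 1L, length(values1) >= 1L,
            all(is.finite(values0)), all(is.finite(values1)))
  n0 <- length(values0)
  n1 <- length(values1)
  r <- rank(c(values0, values1))
  auc <- (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  thr <- c(sort(unique(c(values0, values1))), Inf)
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(c) mean(values0 >= c), numeric(1)),
    tpr = vapply(thr, function(c) mean(values1 >= c), numeric(1))
  )
  structure(list(auc = auc, curve = curve, n0 = n0, n1 = n1),
            class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.3f (n0 = %d, n1 = %d)\n",
              x$auc, x$n0, x$n1))
  invisible(x)
}

#' Univariate logistic regression with Youden-optimal cutoff
#'
#' Fits `P(label = 1 | x)` by maximum-likelihood logistic regression and
#' reports the operating cutoff maximizing the Youden index
#' `J = sensitivity + specificity - 1` on the empirical ROC (ties broken
#' toward the smallest threshold, favouring sensitivity), together with the
#' sensitivity and specificity at that cutoff and the probability-0.5
#' crossing of the fitted curve. Complete separation is flagged
#' (`converged = FALSE`); the ROC-based cutoff is still reported.
#'
#' @param values0,values1 Group value vectors (label 1 assumed larger).
#' @return List with `coefficients` (intercept, slope), `converged`,
#'   `cutoff`, `sensitivity`, `specificity`, `youden`, `p50_crossing`,
#'   `roc`.
#' @export
logistic_cutoff <- function(values0, values1) {
  stopifnot(length(values0) >= 1L, length(values1) >= 1L)
  x <- c(values0, values1)
  y <- c(rep(0L, length(values0)), rep(1L, length(values1)))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- stats::coef(fit)
  converged <- fit$converged && !sep_warn
  p50 <- if (abs(coefs[2]) > .Machine$double.eps) {
    unname(-coefs[1] / coefs[2])
  } else {
    NA_real_
  }
  rc <- roc(values0, values1)
  cv <- rc$curve[is.finite(rc$curve$threshold), ]
  j <- cv$tpr - cv$fpr
  best <- which(j == max(j))[1L]
  list(coefficients = c(intercept = unname(coefs[1]),
                        slope = unname(coefs[2])),
       converged = converged,
       cutoff = cv$threshold[best],
       sensitivity = cv$tpr[best],
       specificity = 1 - cv$fpr[best],
       youden = j[best],
       p50_crossing = p50,
       roc = rc)
}

#' Lesion-subset filters
#'
#' Named subset filters for the analysis cohort: exclusion of lesions in
#' the vicinity of previously treated liver regions (requires a logical
#' `treated_vicinity` column) and restriction to lesions whose mutation
#' status comes from their own biopsy (logical `biopsy_confirmed` column).
#' An empty result or a missing column is an explicit error naming the
#' filter.
#'
#' @param cohort Lesion-level data frame.
#' @param exclude_treated_vicinity Drop `treated_vicinity` lesions.
#' @param biopsy_confirmed_only Keep only `biopsy_confirmed` lesions.
#' @return Filtered data frame.
#' @export
filter_lesions <- function(cohort, exclude_treated_vicinity = FALSE,
                           biopsy_confirmed_only = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (exclude_treated_vicinity) {
    if (!"treated_vicinity" %in% names(cohort)) {
      stop("filter 'exclude_treated_vicinity' needs a 'treated_vicinity' column",
           call. = FALSE)
    }
    cohort <- cohort[!cohort$treated_vicinity, , drop = FALSE]
  }
  if (biopsy_confirmed_only) {
    if (!"biopsy_confirmed" %in% names(cohort)) {
      stop("filter 'biopsy_confirmed_only' needs a 'biopsy_confirmed' column",
           call. = FALSE)
    }
    cohort <- cohort[cohort$biopsy_confirmed, , drop = FALSE]
  }
  if (!nrow(cohort)) {
    stop("no lesions left after subset filtering", call. = FALSE)
  }
  cohort
}

metric_families <- c("suv", "suv_pvec", "suvtlr_pvec", "suv_pvec_time",
                     "sur_time", "sur_pvec_time")

#' Metric-by-correction separation results grid
#'
#' Evaluates every metric family (raw SUV, PVE-corrected SUV, PVE-corrected
#' tumor-to-liver ratio, PVE+time-corrected SUV, time-corrected SUR,
#' PVE+time-corrected SUR) for each statistic (mean/peak/max) and each
#' segmentation tag present, reporting pooled and Welch t-test p values,
#' the Wilcoxon rank-sum p value, AUC, the Youden-optimal cutoff and its
#' sensitivity and specificity. Deterministic given the cohort.
#'
#' @param cohort Corrected cohort from [correct_cohort()] with a 0/1 label
#'   column and (optionally) a `segmentation` tag column.
#' @param label_col Name of the 0/1 label column (default `"label"`).
#' @param families Metric families to evaluate (default all six; raw SUV
#'   columns are `suv_<stat>`, corrected families
#'   `<family>_<stat>`).
#' @param statistics Statistics to evaluate (default mean, peak, max).
#' @param exclude_treated_vicinity,biopsy_confirmed_only Subset filters,
#'   see [filter_lesions()].
#' @return Data frame with one row per (family, statistic, segmentation):
#'   `t_p`, `t_p_welch`, `wilcoxon_p`, `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `n0`, `n1`.
#' @export
build_results_grid <- function(cohort, label_col = "label",
                               families = metric_families,
                               statistics = c("mean", "peak", "max"),
                               exclude_treated_vicinity = FALSE,
                               biopsy_confirmed_only = FALSE) {
  stopifnot(is.data.frame(cohort), label_col %in% names(cohort))
  cohort <- filter_lesions(cohort, exclude_treated_vicinity,
                           biopsy_confirmed_only)
  segs <- if ("segmentation" %in% names(cohort)) {
    unique(cohort$segmentation)
  } else {
    NA_character_
  }
  rows <- list()
  for (seg in segs) {
    sub <- if (is.na(seg)) cohort else
      cohort[cohort$segmentation == seg, , drop = FALSE]
    lab <- sub[[label_col]]
    if (!all(lab %in% c(0, 1))) {
      stop("label column must be 0/1", call. = FALSE)
    }
    if (!any(lab == 0) || !any(lab == 1)) {
      stop("both label groups must be non-empty", call. = FALSE)
    }
    for (fam in families) {
      for (stat in statistics) {
        col <- paste0(fam, "_", stat)
        if (!col %in% names(sub)) {
          stop("cohort lacks metric column '", col, "'", call. = FALSE)
        }
        v0 <- sub[[col]][lab == 0]
        v1 <- sub[[col]][lab == 1]
        lc <- logistic_cutoff(v0, v1)
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, statistic = stat, segmentation = seg,
          t_p = t_test2(v0, v1, "student_pooled")$p_value,
          t_p_welch = t_test2(v0, v1, "welch")$p_value,
          wilcoxon_p = wilcoxon_rank_sum(v0, v1)$p_value,
          auc = lc$roc$auc,
          cutoff = lc$cutoff,
          sensitivity = lc$sensitivity,
          specificity = lc$specificity,
          n0 = length(v0), n1 = length(v1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
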