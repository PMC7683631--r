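# Orchestration: structured configuration and the end-to-end workflows
# (phantom -> RC table, cohort simulation, correction, analysis). These
# functions are the package's command surface; each is a thin composition
# of the module functions and is fully reproducible from its config.

cohort_schema_version <- 1L

#' Pipeline configuration
#'
#' Single structured configuration object for the end-to-end analysis,
#' serializable to JSON. Only the parameters relevant to a given workflow
#' need to be meaningful.
#'
#' @param psf_fwhm_mm PSF full width at half maximum in mm (default 6.5,
#'   a typical post-filtered reconstruction; all wall-correction
#'   magnitudes depend on it).
#' @param model_sbr Sphere-to-background ratio of the RC model (default
#'   2.26).
#' @param wall_mm Phantom sphere wall thickness (default 1).
#' @param peak_voi_ml Peak VOI volume in mL (default 1.0).
#' @param time_mode Uptake-time correction mode (`"approx"` default).
#' @param grouping_policy Amplification grouping policy (default
#'   `"amp_with_wt"`).
#' @param uptake An [uptake_params()] list.
#' @param phantom_noise_sd Relative phantom noise (default 0).
#' @param seed Root seed; module workflows derive fixed substreams from it.
#' @param ... Further named entries stored verbatim (e.g. paths).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(psf_fwhm_mm = 6.5, model_sbr = 2.26,
                            wall_mm = 1, peak_voi_ml = 1.0,
                            time_mode = "approx",
                            grouping_policy = "amp_with_wt",
                            uptake = uptake_params(),
                            phantom_noise_sd = 0, seed = 1L, ...) {
  stopifnot(psf_fwhm_mm > 0, model_sbr > 0, wall_mm >= 0, peak_voi_ml > 0,
            time_mode %in% c("approx", "exact"),
            grouping_policy %in% c("amp_with_wt", "amp_with_mut"),
            phantom_noise_sd >= 0)
  structure(
    c(list(psf_fwhm_mm = psf_fwhm_mm, model_sbr = model_sbr,
           wall_mm = wall_mm, peak_voi_ml = peak_voi_ml,
           time_mode = time_mode, grouping_policy = grouping_policy,
           uptake = unclass(uptake), phantom_noise_sd = phantom_noise_sd,
           seed = as.integer(seed)),
      list(...)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  up <- do.call(uptake_params, lst$uptake)
  lst$uptake <- NULL
  do.call(pipeline_config, c(lst, list(uptake = up)))
}

#' Write / read versioned cohort CSV files
#'
#' Cohort tables are plain CSV preceded by a schema comment line
#' (`# petcorr cohort schema <n>`); the loader rejects unknown schema
#' versions loudly and accepts unversioned plain CSV as the current
#' schema.
#'
#' @param cohort Lesion-level data frame.
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   the data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# petcorr cohort schema %d", cohort_schema_version),
             con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^# petcorr cohort schema", first)) {
    ver <- as.integer(sub("^# petcorr cohort schema\\s+", "", first))
    if (is.na(ver) || ver != cohort_schema_version) {
      stop("unknown cohort schema version: ", first, call. = FALSE)
    }
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Phantom workflow: render a digital phantom and extract RC curves
#'
#' Renders the digital image-quality phantom specified by the config,
#' measures per-sphere recovery coefficients for the mean, peak and max
#' statistics, applies the cold-wall correction and builds the three RC
#' curves. Optionally persists the measured RC table (CSV) and the voxel
#' volume (raw + JSON sidecar).
#'
#' @param config A [pipeline_config()]. Optional entries `rc_table_path`
#'   and `phantom_path` trigger persistence.
#' @param spec Optional [phantom_spec()] override; by default a full
#'   NEMA-like spec is built from the config.
#' @return List with `image` (`phantom_image`), `measured` (per-sphere RC
#'   table for all three statistics) and `curves` (named list of
#'   `rc_curve`).
#' @export
run_phantom <- function(config = pipeline_config(), spec = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  psf <- psf_model(config$psf_fwhm_mm)
  if (is.null(spec)) {
    spec <- phantom_spec(spheres = nema_spheres(wall_mm = config$wall_mm),
                         psf = psf, noise_sd = config$phantom_noise_sd,
                         seed = config$seed)
  }
  image <- render_phantom(spec)
  measured <- do.call(rbind, lapply(c("mean", "peak", "max"), function(s) {
    measure_rc(image, s, peak_voi_ml = config$peak_voi_ml)
  }))
  curves <- rc_curves_from_table(
    data.frame(statistic = measured$statistic,
               inner_diameter_mm = measured$inner_diameter_mm,
               rc_measured = measured$rc),
    psf, wall_mm = config$wall_mm, model_sbr = config$model_sbr,
    peak_voi_ml = config$peak_voi_ml
  )
  if (!is.null(config$rc_table_path)) {
    write_rc_table(curves, config$rc_table_path)
  }
  if (!is.null(config$phantom_path)) write_phantom(image, config$phantom_path)
  list(image = image, measured = measured, curves = curves)
}

#' Correction workflow: apply the correction chain to a cohort table
#'
#' Loads (or accepts) a raw lesion cohort, applies peak fallback and the
#' full correction chain in the pipeline order, and optionally writes the
#' wide corrected table.
#'
#' @param config A [pipeline_config()]; optional entries `cohort_path`
#'   (input CSV, used when `cohort` is `NULL`) and `corrected_path`
#'   (output CSV).
#' @param cohort Raw lesion data frame (overrides `cohort_path`).
#' @param rc_curves Named list of `rc_curve` objects; when `NULL`, the
#'   curves are rebuilt from the config's `rc_table_path`.
#' @return The corrected cohort data frame.
#' @export
run_correct <- function(config = pipeline_config(), cohort = NULL,
                        rc_curves = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$cohort_path)) {
      stop("no cohort given and no 'cohort_path' in config", call. = FALSE)
    }
    cohort <- read_cohort_csv(config$cohort_path)
  }
  if (is.null(rc_curves)) {
    if (is.null(config$rc_table_path)) {
      stop("no RC curves given and no 'rc_table_path' in config",
           call. = FALSE)
    }
    rc_curves <- rc_curves_from_table(
      read_rc_table(config$rc_table_path), psf_model(config$psf_fwhm_mm),
      wall_mm = config$wall_mm, model_sbr = config$model_sbr,
      peak_voi_ml = config$peak_voi_ml
    )
  }
  corrected <- correct_cohort(
    cohort, rc_curves, do.call(uptake_params, config$uptake),
    mode = config$time_mode, peak_voi_ml = config$peak_voi_ml
  )
  if (!is.null(config$corrected_path)) {
    write_cohort_csv(corrected, config$corrected_path)
  }
  corrected
}

#' Analysis workflow: labels, subset filters and the results grid
#'
#' Parses the cohort's annotation strings (column `kras_annotation`; a
#' ready-made 0/1 `label` column is used as-is), assigns binary labels
#' under the configured amplification grouping policy and builds the full
#' metric-by-correction results grid.
#'
#' @param config A [pipeline_config()]; optional `results_path` writes the
#'   grid as CSV.
#' @param cohort Corrected cohort data frame (or `NULL` to read
#'   `config$corrected_path`).
#' @param families,statistics Passed to [build_results_grid()].
#' @param exclude_treated_vicinity,biopsy_confirmed_only Subset filters.
#' @return The results-grid data frame.
#' @export
run_analyze <- function(config = pipeline_config(), cohort = NULL,
                        families = metric_families,
                        statistics = c("mean", "peak", "max"),
                        exclude_treated_vicinity = FALSE,
                        biopsy_confirmed_only = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$corrected_path)) {
      stop("no cohort given and no 'corrected_path' in config",
           call. = FALSE)
    }
    cohort <- read_cohort_csv(config$corrected_path)
  }
  if (!"label" %in% names(cohort)) {
    if (!"kras_annotation" %in% names(cohort)) {
      stop("cohort needs a 'label' or 'kras_annotation' column",
           call. = FALSE)
    }
    parsed <- parse_kras(cohort$kras_annotation)
    cohort$label <- kras_labels(parsed, config$grouping_policy)
  }
  grid <- build_results_grid(
    cohort, families = families, statistics = statistics,
    exclude_treated_vicinity = exclude_treated_vicinity,
    biopsy_confirmed_only = biopsy_confirmed_only
  )
  if (!is.null(config$results_path)) {
    utils::write.csv(grid, config$results_path, row.names = FALSE)
  }
  grid
}

#' Replicate-averaged AUC from published group moments
#'
#' Simulates the summary-matched cohort for one metric family, statistic
#' and segmentation arm and averages the empirical AUC over seeded
#' replicates — the reconstruction used to check the headline
#' discriminative performance against its published value.
#'
#' @param family,segmentation,statistic Metric selector (defaults: fully
#'   corrected SUR, threshold segmentation arm, max statistic).
#' @param params A [cohort_params()].
#' @param n_replicates Number of replicates (default 1000).
#' @param seed Root seed; replicate `i` uses `seed + i - 1`.
#' @return List with `mean_auc`, `sd_auc`, `n_replicates`, `n0`, `n1`.
#' @export
replicate_auc <- function(family = "sur_pvec_time",
                          segmentation = "hermes", statistic = "max",
                          params = cohort_params(), n_replicates = 1000L,
                          seed = 1L) {
  moments <- table3_moments()
  col <- paste0(family, "_", statistic)
  aucs <- vapply(seq_len(n_replicates), function(i) {
    coh <- generate_summary_matched(params, family, segmentation,
                                    statistics = statistic,
                                    moments = moments,
                                    seed = seed + i - 1L)
    roc(coh[[col]][coh$label == 0], coh[[col]][coh$label == 1])$auc
  }, numeric(1))
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
       n_replicates = n_replicates, n0 = params$n_wt, n1 = params$n_mut)
}
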