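#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: either a
#' synthetic-cohort block or a path to an existing cohort CSV, the stochastic
#' model's bandwidth rule, the metric thresholds, and the output directory.
#'
#' @param cohort A [cohort_config()] for synthetic input, or a path to a
#'   cohort CSV (columns `patient_id, diagnosis, time_min, si_value`).
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed used for synthetic generation.
#' @param bandwidth_rule Bandwidth rule for [fit_stochastic_model()].
#' @param threshold One-sided exceedance threshold in (0, 1).
#' @param time_cap_min Time cap for the mixed-model observations, minutes.
#' @param metric Which mixed models to fit.
#' @param fit_mixed_models Set `FALSE` to stop after the descriptive tables
#'   (useful for very small cohorts).
#' @param verbose Emit stage messages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            outdir = tempfile("sivar_run_"),
                            seed = 1L,
                            bandwidth_rule = "silverman",
                            threshold = 0.9,
                            time_cap_min = 8000,
                            metric = c("both", "quadratic", "one_sided"),
                            fit_mixed_models = TRUE,
                            verbose = TRUE) {
  metric <- match.arg(metric)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("invalid pipeline configuration: field 'threshold' must lie in (0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(time_cap_min) || time_cap_min <= 0) {
    stop("invalid pipeline configuration: field 'time_cap_min' must be > 0",
         call. = FALSE)
  }
  if (inherits(cohort, "cohort_config")) {
    validate_cohort_config(cohort)
  } else if (!(is.character(cohort) && length(cohort) == 1)) {
    stop("invalid pipeline configuration: field 'cohort' must be a cohort_config or a CSV path",
         call. = FALSE)
  }
  structure(list(cohort = cohort, outdir = outdir, seed = as.integer(seed),
                 bandwidth_rule = bandwidth_rule, threshold = threshold,
                 time_cap_min = time_cap_min, metric = metric,
                 fit_mixed_models = isTRUE(fit_mixed_models),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.stage_msg <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

.write_artifact <- function(tab, dir, name, manifest) {
  path <- file.path(dir, name)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  rbind(manifest, data.frame(file = name,
                             rows = nrow(tab),
                             md5 = unname(tools::md5sum(path)),
                             stringsAsFactors = FALSE))
}

.mixed_coef_table <- function(result) {
  data.frame(term = c(names(result$fixed), "time_per_min", "time_per_day"),
             estimate = c(unname(result$fixed), result$time_per_min,
                          result$time_per_day),
             stringsAsFactors = FALSE)
}

#' Run the full variability-analysis pipeline
#'
#' Executes, in order: cohort generation (or ingestion), stochastic-model
#' fitting on all pooled hourly transitions, percentile scoring, day-of-stay
#' segmentation, penalty aggregation, descriptive tables (decile coverage
#' histograms with uniformity statistics, LOWESS trends, distribution
#' summaries), mixed-effects fits with post-hoc Tukey contrasts and the
#' model-selection tests, and writes every artifact as CSV plus a manifest
#' with MD5 checksums. Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output directory, the manifest, and
#'   the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), rows = integer(),
                         md5 = character(), stringsAsFactors = FALSE)

  .stage_msg(config, "[1/6] cohort")
  cohort <- if (inherits(config$cohort, "cohort_config")) {
    cfg <- config$cohort
    cfg$seed <- config$seed
    generate_cohort(cfg)
  } else {
    read_cohort_csv(config$cohort)
  }
  write_cohort_csv(cohort, file.path(config$outdir, "cohort.csv"))
  manifest <- rbind(manifest,
                    data.frame(file = "cohort.csv",
                               rows = nrow(as_cohort_table(cohort)),
                               md5 = unname(tools::md5sum(
                                 file.path(config$outdir, "cohort.csv")))))

  .stage_msg(config, "[2/6] stochastic model")
  pairs <- extract_transitions(cohort)
  model <- fit_stochastic_model(pairs, bandwidth_rule = config$bandwidth_rule)
  write_stochastic_model(model, file.path(config$outdir, "stochastic_model.csv"))
  manifest <- rbind(manifest,
                    data.frame(file = "stochastic_model.csv",
                               rows = model$n_transitions,
                               md5 = unname(tools::md5sum(
                                 file.path(config$outdir, "stochastic_model.csv")))))

  .stage_msg(config, "[3/6] percentiles + segmentation")
  seg <- segmented_percentiles(cohort, model)
  seg_out <- seg
  seg_out$percentile <- sprintf("%.10g", seg_out$percentile)
  manifest <- .write_artifact(seg_out, config$outdir, "percentiles.csv", manifest)

  .stage_msg(config, "[4/6] penalties")
  penalties <- per_patient_day_scores(cohort, model, threshold = config$threshold)
  pen_out <- penalties
  pen_out$quadratic <- sprintf("%.10g", pen_out$quadratic)
  pen_out$one_sided <- sprintf("%.10g", pen_out$one_sided)
  manifest <- .write_artifact(pen_out, config$outdir, "penalties.csv", manifest)

  .stage_msg(config, "[5/6] descriptive tables")
  hist_tab <- decile_histogram_table(seg)
  manifest <- .write_artifact(hist_tab, config$outdir,
                              "decile_histograms.csv", manifest)
  unif <- do.call(rbind, lapply(split(hist_tab,
                                      list(hist_tab$day, hist_tab$diagnosis),
                                      drop = TRUE), function(d) {
    u <- suppressWarnings(uniformity_statistic(
      list(counts = d$count, n = d$n[1])))
    data.frame(day = d$day[1], diagnosis = d$diagnosis[1], n = d$n[1],
               statistic = u$statistic, p_value = u$p_value,
               small_sample = u$small_sample, stringsAsFactors = FALSE)
  }))
  manifest <- .write_artifact(unif, config$outdir,
                              "uniformity_tests.csv", manifest)
  hour_scores <- data.frame(time_min = seg$time_min,
                            value = (seg$percentile - 0.5)^2,
                            diagnosis = seg$diagnosis)
  trends <- lowess_trend(hour_scores)
  manifest <- .write_artifact(trends, config$outdir, "lowess_trends.csv",
                              manifest)
  summaries <- distribution_summary(penalties)
  manifest <- .write_artifact(summaries$summary, config$outdir,
                              "score_summaries.csv", manifest)
  manifest <- .write_artifact(summaries$density, config$outdir,
                              "score_densities.csv", manifest)

  results <- list(cohort = cohort, model = model, percentiles = seg,
                  penalties = penalties, histograms = hist_tab,
                  uniformity = unif, trends = trends, summaries = summaries)

  if (config$fit_mixed_models) {
    .stage_msg(config, "[6/6] mixed models")
    if (config$metric %in% c("both", "quadratic")) {
      obs_q <- build_observations(seg, "quadratic",
                                  time_cap_min = config$time_cap_min)
      lme_fit <- fit_lme_quadratic(obs_q)
      results$lme_quadratic <- lme_fit
      if (lme_fit$converged) {
        manifest <- .write_artifact(.mixed_coef_table(lme_fit), config$outdir,
                                    "lme_quadratic_coefficients.csv", manifest)
        tk <- tukey_hsd(lme_fit)
        results$tukey_quadratic <- tk
        manifest <- .write_artifact(tk, config$outdir,
                                    "tukey_quadratic.csv", manifest)
      }
    }
    if (config$metric %in% c("both", "one_sided")) {
      obs_o <- build_observations(seg, "one_sided",
                                  time_cap_min = config$time_cap_min,
                                  threshold = config$threshold)
      glme_fit <- fit_glme_onesided(obs_o)
      results$glme_onesided <- glme_fit
      if (!is.null(glme_fit$fit)) {
        manifest <- .write_artifact(.mixed_coef_table(glme_fit), config$outdir,
                                    "glme_onesided_coefficients.csv", manifest)
        tk <- tukey_hsd(glme_fit)
        results$tukey_onesided <- tk
        manifest <- .write_artifact(tk, config$outdir,
                                    "tukey_onesided.csv", manifest)
      }
    }
  } else {
    .stage_msg(config, "[6/6] mixed models skipped by config")
  }

  utils::write.csv(manifest, file.path(config$outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  results$manifest <- manifest
  results$outdir <- config$outdir
  invisible(results)
}

#' Generate the bundled miniature fixture cohort
#'
#' Writes a deterministic miniature cohort (12 patients, two per diagnosis
#' group, short stays) together with its percentile and penalty tables, as
#' produced by the package's own pipeline. The copies bundled under
#' `inst/extdata/` are golden files: regenerating with the same seed must
#' reproduce them.
#'
#' @param seed Integer seed (the bundled files use 42).
#' @param dir Output directory.
#' @return Invisibly, the paths of the three files written.
#' @export
make_fixtures <- function(seed = 42L, dir = tempfile("sivar_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort_config(n_patients_per_group = 2,
                       los_hours_log_mean = log(40),
                       los_hours_log_sd = 0.3,
                       seed = seed)
  cohort <- generate_cohort(cfg)
  model <- fit_stochastic_model(extract_transitions(cohort))
  recs <- cohort_percentiles(model, cohort)
  penalties <- per_patient_day_scores(cohort, model)
  paths <- c(cohort = file.path(dir, "mini_cohort.csv"),
             percentiles = file.path(dir, "mini_percentiles.csv"),
             penalties = file.path(dir, "mini_penalties.csv"))
  write_cohort_csv(cohort, paths["cohort"])
  recs$percentile <- sprintf("%.10g", recs$percentile)
  utils::write.csv(recs, paths["percentiles"], row.names = FALSE, quote = FALSE)
  penalties$quadratic <- sprintf("%.10g", penalties$quadratic)
  penalties$one_sided <- sprintf("%.10g", penalties$one_sided)
  utils::write.csv(penalties, paths["penalties"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
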