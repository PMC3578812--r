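#' Diagnosis group labels
#'
#' The six APACHE III-derived diagnosis groups used throughout the package:
#' operative (`Op`) and non-operative (`NOp`) crossed with cardiac (`C`),
#' gastric (`G`) and all-other (`O`).
#'
#' @return Character vector of the six labels, in canonical order.
#' @export
diagnosis_groups <- function() {
  c("NOpC", "OpC", "NOpG", "OpG", "NOpO", "OpO")
}

#' Configuration for the synthetic SI cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates hourly model-based insulin sensitivity (SI) series:
#' positive and right-skewed, with a per-patient random baseline and random
#' linear drift on the log scale, hour-to-hour innovations whose standard
#' deviation is largest on day 1 of ICU stay and decays multiplicatively with
#' each further day, and diagnosis-group-specific variability multipliers
#' (gastric lowest, cardiac highest by default).
#'
#' @param n_patients_per_group Positive integer, patients simulated per
#'   diagnosis group.
#' @param group_labels Character vector of exactly 6 unique diagnosis labels.
#' @param los_hours_log_mean,los_hours_log_sd Lognormal parameters of length
#'   of stay in hours. Defaults give a median stay of 96 h with stays from
#'   about a day to beyond 5.5 days.
#' @param si_baseline_log_mean,si_baseline_log_sd Lognormal parameters of the
#'   per-patient SI baseline, on the log scale of SI in nominal units of
#'   1e-4 L/mU/min.
#' @param innovation_sd_day1 Per-hour innovation SD of log SI at admission.
#' @param innovation_decay_per_day Multiplicative decay of the innovation SD
#'   per 24 h of stay, in (0, 1].
#' @param group_variability_multiplier Named numeric vector mapping each group
#'   label to a positive factor scaling its innovation SD.
#' @param trend_sd SD of the per-patient random slope of log SI per hour.
#' @param min_los_hours Minimum length of stay; draws below it are rejected
#'   and redrawn so every patient qualifies for daily statistics (default 24 h).
#' @param include_short If `TRUE`, disable the minimum-stay truncation so that
#'   sub-24-h patients are emitted (to exercise exclusion paths downstream).
#' @param seed Integer master seed. One per-patient substream is spawned from
#'   it, so cohorts are reproducible under patient reordering.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients_per_group = 50,
                          group_labels = diagnosis_groups(),
                          los_hours_log_mean = log(96),
                          los_hours_log_sd = 0.6,
                          si_baseline_log_mean = log(3),
                          si_baseline_log_sd = 0.5,
                          innovation_sd_day1 = 0.25,
                          innovation_decay_per_day = 0.7,
                          group_variability_multiplier = c(
                            NOpC = 1.25, OpC = 1.2, NOpG = 0.8,
                            OpG = 0.9, NOpO = 1.0, OpO = 1.0
                          ),
                          trend_sd = 0.002,
                          min_los_hours = 24,
                          include_short = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_patients_per_group = n_patients_per_group,
    group_labels = as.character(group_labels),
    los_hours_log_mean = los_hours_log_mean,
    los_hours_log_sd = los_hours_log_sd,
    si_baseline_log_mean = si_baseline_log_mean,
    si_baseline_log_sd = si_baseline_log_sd,
    innovation_sd_day1 = innovation_sd_day1,
    innovation_decay_per_day = innovation_decay_per_day,
    group_variability_multiplier = group_variability_multiplier,
    trend_sd = trend_sd,
    min_los_hours = min_los_hours,
    include_short = isTRUE(include_short),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

.config_stop <- function(field, msg) {
  stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

#' Validate a cohort configuration
#'
#' @param cfg A `cohort_config` object (or bare list with the same fields).
#' @return `cfg`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_cohort_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_patients_per_group) || cfg$n_patients_per_group < 1 ||
      cfg$n_patients_per_group != floor(cfg$n_patients_per_group)) {
    .config_stop("n_patients_per_group", "must be a positive integer")
  }
  if (length(cfg$group_labels) != 6L || anyDuplicated(cfg$group_labels)) {
    .config_stop("group_labels", "must hold exactly 6 unique labels")
  }
  for (f in c("los_hours_log_sd", "si_baseline_log_sd")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0) .config_stop(f, "must be > 0")
  }
  if (!num1(cfg$innovation_sd_day1) || cfg$innovation_sd_day1 < 0) {
    .config_stop("innovation_sd_day1", "must be >= 0")
  }
  for (f in c("los_hours_log_mean", "si_baseline_log_mean")) {
    if (!num1(cfg[[f]])) .config_stop(f, "must be a finite number")
  }
  if (!num1(cfg$trend_sd) || cfg$trend_sd < 0) {
    .config_stop("trend_sd", "must be >= 0")
  }
  if (!num1(cfg$innovation_decay_per_day) ||
      cfg$innovation_decay_per_day <= 0 || cfg$innovation_decay_per_day > 1) {
    .config_stop("innovation_decay_per_day", "must lie in (0, 1]")
  }
  mult <- cfg$group_variability_multiplier
  if (!is.numeric(mult) || is.null(names(mult)) ||
      !setequal(names(mult), cfg$group_labels) || any(mult < 0)) {
    .config_stop("group_variability_multiplier",
                 "must be a nonnegative vector named by all 6 group labels")
  }
  if (!num1(cfg$min_los_hours) || cfg$min_los_hours < 1) {
    .config_stop("min_los_hours", "must be >= 1")
  }
  if (!num1(cfg$seed)) .config_stop("seed", "must be an integer")
  invisible(cfg)
}

## innovation SD at the transition leaving time t_min (log-SI scale, per hour)
.innovation_sd <- function(cfg, t_min, multiplier) {
  cfg$innovation_sd_day1 *
    cfg$innovation_decay_per_day^(t_min / 1440) * multiplier
}

#' Generate a synthetic cohort of hourly SI trajectories
#'
#' Simulates one SI trajectory per patient as a lognormal random walk with
#' drift: `log SI(t+60) = log SI(t) + slope + eta_t` with
#' `eta_t ~ N(0, sd(t)^2)`, where `sd(t)` decays with day of stay and is
#' scaled by the patient's diagnosis-group multiplier. Baselines are
#' lognormal, slopes normal, lengths of stay lognormal and (by default)
#' truncated to at least 24 h by rejection. Fully deterministic given the
#' config seed; each patient consumes an independent substream.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `si_cohort`: a list with `trajectories` (list of
#'   `si_trajectory`, each with `patient_id`, `diagnosis`, `times_min`,
#'   `si_values`) and `provenance` (the config).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients_per_group = 2, seed = 7))
#' length(cohort$trajectories)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  labels <- config$group_labels
  n_total <- config$n_patients_per_group * length(labels)
  ## per-patient substream seeds from the master seed
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_total)
  trajectories <- vector("list", n_total)
  k <- 0L
  for (g in labels) {
    mult <- config$group_variability_multiplier[[g]]
    for (i in seq_len(config$n_patients_per_group)) {
      k <- k + 1L
      set.seed(sub_seeds[k])
      los_h <- stats::rlnorm(1, config$los_hours_log_mean, config$los_hours_log_sd)
      if (!config$include_short) {
        tries <- 0L
        while (los_h < config$min_los_hours && tries < 1000L) {
          los_h <- stats::rlnorm(1, config$los_hours_log_mean, config$los_hours_log_sd)
          tries <- tries + 1L
        }
        los_h <- max(los_h, config$min_los_hours)
      }
      n_hours <- max(1L, floor(los_h))
      times <- seq(0L, n_hours * 60L, by = 60L)
      base_log <- stats::rnorm(1, config$si_baseline_log_mean, config$si_baseline_log_sd)
      slope <- stats::rnorm(1, 0, config$trend_sd)
      sds <- .innovation_sd(config, times[-length(times)], mult)
      eta <- stats::rnorm(n_hours, 0, sds)
      log_si <- base_log + cumsum(c(0, slope + eta))
      trajectories[[k]] <- si_trajectory(
        patient_id = sprintf("%s_%03d", g, i),
        diagnosis = g,
        times_min = times,
        si_values = exp(log_si)
      )
    }
  }
  new_si_cohort(trajectories, provenance = config)
}

#' Construct a single SI trajectory
#'
#' @param patient_id Unique patient identifier.
#' @param diagnosis Diagnosis group label.
#' @param times_min Strictly increasing minutes from admission, hourly
#'   (60-min) spacing starting at 0.
#' @param si_values Positive SI values, one per time point (nominal units
#'   1e-4 L/mU/min).
#' @return An `si_trajectory` object.
#' @export
si_trajectory <- function(patient_id, diagnosis, times_min, si_values) {
  if (length(times_min) != length(si_values)) {
    stop("times_min and si_values must have equal length", call. = FALSE)
  }
  if (length(si_values) >= 1 && any(si_values <= 0)) {
    stop("all si_values must be strictly positive", call. = FALSE)
  }
  if (length(times_min) >= 2 && any(diff(times_min) != 60)) {
    stop("times_min must be hourly (60-minute) spaced", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         diagnosis = as.character(diagnosis),
         times_min = as.numeric(times_min),
         si_values = as.numeric(si_values)),
    class = "si_trajectory"
  )
}

new_si_cohort <- function(trajectories, provenance = NULL) {
  ids <- vapply(trajectories, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) {
    stop("patient_id must be unique across trajectories", call. = FALSE)
  }
  structure(list(trajectories = trajectories, provenance = provenance),
            class = "si_cohort")
}

#' @export
print.si_cohort <- function(x, ...) {
  n_hours <- sum(vapply(x$trajectories, function(tr) length(tr$si_values), 0L))
  cat(sprintf("si_cohort: %d patients, %d hourly observations\n",
              length(x$trajectories), n_hours))
  invisible(x)
}

#' Convert a cohort to/from the long trajectory table
#'
#' The on-disk interchange format is a long table with columns
#' `patient_id, diagnosis, time_min, si_value`.
#'
#' @param cohort An `si_cohort`.
#' @return `as_cohort_table()`: a data frame in the long format.
#' @export
as_cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort$trajectories, function(tr) {
    data.frame(patient_id = tr$patient_id, diagnosis = tr$diagnosis,
               time_min = tr$times_min, si_value = tr$si_values,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname as_cohort_table
#' @param table Long-format data frame with the four interchange columns.
#' @return `cohort_from_table()`: an `si_cohort`.
#' @export
cohort_from_table <- function(table) {
  need <- c("patient_id", "diagnosis", "time_min", "si_value")
  if (!all(need %in% names(table))) {
    stop("cohort table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  trajectories <- lapply(split(table, table$patient_id), function(d) {
    d <- d[order(d$time_min), ]
    si_trajectory(d$patient_id[1], d$diagnosis[1], d$time_min, d$si_value)
  })
  ## preserve first-appearance order rather than split()'s alphabetical order
  first <- tapply(seq_len(nrow(table)), table$patient_id, min)
  trajectories <- trajectories[order(first[names(trajectories)])]
  names(trajectories) <- NULL
  new_si_cohort(trajectories)
}

#' Read/write a cohort as CSV
#'
#' @param cohort An `si_cohort`.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns an `si_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- as_cohort_table(cohort)
  tab$si_value <- sprintf("%.10g", tab$si_value)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort_from_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Sample a self-consistent null cohort from a fitted stochastic model
#'
#' Each trajectory starts at an SI value drawn from the model's marginal
#' distribution of current-SI kernel centres and evolves by repeated draws
#' from the fitted conditional next-hour distribution. Scoring such a cohort
#' with the same model yields percentiles that are uniform on \[0, 1\] by the
#' probability integral transform, which is the calibration reference used by
#' the coverage histograms and penalty nulls.
#'
#' @param model A fitted `si_stochastic_model`.
#' @param n_patients Number of trajectories to draw.
#' @param horizon_hours Trajectory length in hourly observations (>= 2).
#' @param seed Integer seed.
#' @return An `si_cohort`. Diagnosis labels cycle through the six canonical
#'   groups so grouped summaries remain exercisable.
#' @export
sample_null_cohort <- function(model, n_patients, horizon_hours, seed) {
  assert_stochastic_model(model)
  if (horizon_hours < 2) stop("horizon_hours must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  labels <- rep_len(diagnosis_groups(), n_patients)
  ## marginal of current-SI: the u-coordinate KDE (centre + kernel jitter)
  idx <- sample.int(model$n_transitions, n_patients, replace = TRUE)
  si <- exp(stats::rnorm(n_patients, model$centres_u[idx], model$bandwidth_u[idx]))
  series <- matrix(0, nrow = horizon_hours, ncol = n_patients)
  series[1, ] <- si
  for (h in 2:horizon_hours) {
    series[h, ] <- sample_next(model, series[h - 1, ])
  }
  times <- seq(0L, (horizon_hours - 1L) * 60L, by = 60L)
  trajectories <- lapply(seq_len(n_patients), function(j) {
    si_trajectory(sprintf("null_%04d", j), labels[j], times, series[, j])
  })
  new_si_cohort(trajectories, provenance = list(null_model = TRUE, seed = seed))
}

#' Read/write a cohort config as a flat YAML file
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$group_variability_multiplier <- as.list(x$group_variability_multiplier)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$group_variability_multiplier <- unlist(x$group_variability_multiplier)
  do.call(cohort_config, x)
}
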