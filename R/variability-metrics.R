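#' Percentile (PIT) series of a trajectory under the stochastic model
#'
#' For each consecutive hourly pair `(SI_n, SI_{n+1})` of one patient,
#' evaluates the percentile of the observed next-hour value on its predicted
#' distribution, `p = F(SI_{n+1} | SI_n)`. Each record is timestamped at the
#' *observed* (n+1)-th hour; the first hour of a stay has no predecessor and
#' yields no record. Under a perfectly calibrated model the percentiles are
#' uniform on \[0, 1\] (probability integral transform).
#'
#' @param model A fitted `si_stochastic_model`.
#' @param trajectory An `si_trajectory`.
#' @return Data frame `patient_id, diagnosis, time_min, percentile`; zero
#'   rows when the trajectory is shorter than 2 observations.
#' @export
percentile_series <- function(model, trajectory) {
  assert_stochastic_model(model)
  n <- length(trajectory$si_values)
  if (n < 2) {
    return(data.frame(patient_id = character(), diagnosis = character(),
                      time_min = numeric(), percentile = numeric()))
  }
  p <- batch_percentiles(model, trajectory$si_values[-n],
                         trajectory$si_values[-1])
  data.frame(patient_id = trajectory$patient_id,
             diagnosis = trajectory$diagnosis,
             time_min = trajectory$times_min[-1],
             percentile = p,
             stringsAsFactors = FALSE)
}

#' Percentile series for a whole cohort
#'
#' @param cohort An `si_cohort`.
#' @inheritParams percentile_series
#' @return Row-bound percentile records of every trajectory.
#' @export
cohort_percentiles <- function(model, cohort) {
  out <- do.call(rbind, lapply(cohort$trajectories, function(tr) {
    percentile_series(model, tr)
  }))
  rownames(out) <- NULL
  out
}

#' Quadratic variability penalty
#'
#' Mean squared deviation of the percentiles from the ideal 50th percentile:
#' `mean((p - 0.5)^2)`, in \[0, 0.25\]. Measures overall intra-patient
#' variability relative to the whole-cohort model; 0 for a patient always at
#' the predicted median, 1/12 for perfectly calibrated (uniform) percentiles,
#' 0.25 for percentiles pinned at 0 or 1.
#'
#' @param percentiles Numeric vector of percentiles in \[0, 1\]; nonempty.
#' @return The penalty value.
#' @export
quadratic_penalty <- function(percentiles) {
  .check_percentiles(percentiles)
  mean((percentiles - 0.5)^2)
}

#' One-sided threshold penalty
#'
#' Fraction of percentiles strictly exceeding the threshold (default the
#' 90th percentile of the predicted distribution). Counts large upward SI
#' swings — the ones that can induce hypoglycemia when insulin is dosed on
#' the current SI value. Values above the threshold's tail mass (10% at the
#' default) flag above-reference risk.
#'
#' @inheritParams quadratic_penalty
#' @param threshold Exceedance threshold in (0, 1); strict inequality.
#' @return Fraction in \[0, 1\].
#' @export
one_sided_penalty <- function(percentiles, threshold = 0.9) {
  .check_percentiles(percentiles)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  mean(percentiles > threshold)
}

.check_percentiles <- function(p) {
  if (length(p) == 0) {
    stop("cannot aggregate an empty percentile list", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1) || any(!is.finite(p))) {
    stop("percentiles must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Day-of-stay blocks
#'
#' @return Data frame of the four analysis blocks: day1 = \[0, 1440) min,
#'   day2 = \[1440, 2880), day3 = \[2880, 4320), day4plus = \[4320, Inf).
#' @export
day_blocks <- function() {
  data.frame(label = c("day1", "day2", "day3", "day4plus"),
             start_min = c(0, 1440, 2880, 4320),
             end_min = c(1440, 2880, 4320, Inf),
             stringsAsFactors = FALSE)
}

#' Segment one patient's percentile records into day-of-stay blocks
#'
#' Records are assigned by the observed hour's timestamp. To avoid unequal
#' weighting from patient discharge, day 1/2/3 are retained only when the
#' stay covers the complete 24-h block; day 4+ keeps all records past
#' 4320 min regardless of completeness. Patients staying under 24 h are
#' excluded entirely (empty result).
#'
#' @param records Percentile records of a *single* patient.
#' @param los_min Length of stay in minutes (time of the last observation).
#' @return Named list of record subsets, one element per populated block.
#' @export
segment_days <- function(records, los_min) {
  if (nrow(records) > 0 && length(unique(records$patient_id)) > 1) {
    stop("segment_days expects records from a single patient", call. = FALSE)
  }
  if (los_min < 1440) return(list())
  blocks <- day_blocks()
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (is.finite(b$end_min) && los_min < b$end_min) next
    keep <- records$time_min >= b$start_min & records$time_min < b$end_min
    if (any(keep)) out[[b$label]] <- records[keep, , drop = FALSE]
  }
  out
}

#' Per-patient, per-day penalty scores for a cohort
#'
#' Runs [percentile_series()] and [segment_days()] for every patient and
#' aggregates each populated day block with [quadratic_penalty()] and
#' [one_sided_penalty()].
#'
#' @param cohort An `si_cohort`.
#' @param model A fitted `si_stochastic_model`.
#' @param threshold Exceedance threshold passed to [one_sided_penalty()].
#' @return Data frame `patient_id, diagnosis, day, quadratic, one_sided,
#'   n_hours` with one row per (patient, populated day block).
#' @export
per_patient_day_scores <- function(cohort, model, threshold = 0.9) {
  assert_stochastic_model(model)
  rows <- lapply(cohort$trajectories, function(tr) {
    recs <- percentile_series(model, tr)
    segs <- segment_days(recs, los_min = max(tr$times_min))
    if (length(segs) == 0) return(NULL)
    do.call(rbind, lapply(names(segs), function(lab) {
      p <- segs[[lab]]$percentile
      data.frame(patient_id = tr$patient_id, diagnosis = tr$diagnosis,
                 day = lab,
                 quadratic = quadratic_penalty(p),
                 one_sided = one_sided_penalty(p, threshold),
                 n_hours = length(p),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), diagnosis = character(),
                      day = character(), quadratic = numeric(),
                      one_sided = numeric(), n_hours = integer())
  }
  rownames(out) <- NULL
  out
}

#' Write/read penalty and percentile tables as CSV
#'
#' @param x Table returned by [per_patient_day_scores()] or
#'   [cohort_percentiles()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
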