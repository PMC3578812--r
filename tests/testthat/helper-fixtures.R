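# Shared fixtures, built in code at test time.

# small generated cohort: 3 patients/group, moderate stays
tiny_cohort <- function(seed = 11, n_per_group = 3, los_med_h = 48) {
  generate_cohort(cohort_config(
    n_patients_per_group = n_per_group,
    los_hours_log_mean = log(los_med_h),
    los_hours_log_sd = 0.3,
    seed = seed
  ))
}

# model fitted on a tiny cohort's pooled transitions
tiny_model <- function(seed = 11, ...) {
  fit_stochastic_model(extract_transitions(tiny_cohort(seed = seed, ...)))
}

# hand-built hourly trajectory from explicit SI values
manual_trajectory <- function(si, id = "p1", diagnosis = "NOpO") {
  si_trajectory(id, diagnosis, seq(0, by = 60, length.out = length(si)), si)
}

# percentile-record frame for metric-level tests
manual_records <- function(p, t = seq(60, by = 60, length.out = length(p)),
                           id = "p1", diagnosis = "NOpO") {
  data.frame(patient_id = rep_len(id, length(p)),
             diagnosis = rep_len(diagnosis, length(p)),
             time_min = t, percentile = p, stringsAsFactors = FALSE)
}

# data simulated directly from the cell-means LME equation (independent of
# the percentile pipeline): y = beta[group] + beta_t_day * t_day + b0 + b1*t
simulate_lme_data <- function(n_per_group = 10, hours = 48,
                              beta = c(NOpC = -0.5, OpC = -0.45, NOpG = -1.0,
                                       OpG = -0.7, NOpO = -0.74, OpO = -0.85),
                              beta_t_day = -0.18,
                              sd_b0 = 0.3, sd_b1 = 0.05, sd_e = 0.5,
                              seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(beta)) {
    for (i in seq_len(n_per_group)) {
      t_min <- seq(60, hours * 60, by = 60)
      t_day <- t_min / 1440
      b0 <- rnorm(1, 0, sd_b0)
      b1 <- rnorm(1, 0, sd_b1)
      y <- beta[[g]] + beta_t_day * t_day + b0 + b1 * t_day +
        rnorm(length(t_day), 0, sd_e)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("%s_%02d", g, i), diagnosis = g,
        time_min = t_min, time_day = t_day, response = y,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$patient_id <- factor(out$patient_id)
  out$diagnosis <- factor(out$diagnosis,
                          levels = intersect(diagnosis_groups(), names(beta)))
  attr(out, "metric") <- "quadratic"
  out
}

# binary-response analogue on the logit scale
simulate_glme_data <- function(n_per_group = 10, hours = 48,
                               beta = c(NOpC = -1.6, OpC = -1.9, NOpG = -2.35,
                                        OpG = -1.9, NOpO = -2.0, OpO = -2.1),
                               beta_t_day = -0.12, sd_b0 = 0.4, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(beta)) {
    for (i in seq_len(n_per_group)) {
      t_min <- seq(60, hours * 60, by = 60)
      t_day <- t_min / 1440
      b0 <- rnorm(1, 0, sd_b0)
      eta <- beta[[g]] + beta_t_day * t_day + b0
      y <- rbinom(length(eta), 1, plogis(eta))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("%s_%02d", g, i), diagnosis = g,
        time_min = t_min, time_day = t_day, response = y,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$patient_id <- factor(out$patient_id)
  out$diagnosis <- factor(out$diagnosis,
                          levels = intersect(diagnosis_groups(), names(beta)))
  attr(out, "metric") <- "one_sided"
  out
}
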