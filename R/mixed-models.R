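#' Build per-hour model observations from percentile records
#'
#' Converts percentile records into the observation table used by the
#' mixed-effects models. The analysis is restricted to the roughly linear
#' early phase of stay by dropping observations beyond `time_cap_min`
#' (default 8000 min, about the first 5.5 days).
#'
#' Responses:
#' * `quadratic` — the per-hour squared percentile deviation `(p - 0.5)^2`,
#'   rescaled by 4 to map its \[0, 0.25\] support onto (0, 1), clamped to
#'   `[eps, 1 - eps]`, then logit-transformed. The logit maps the skewed
#'   bounded score to an approximately normal scale for the LME.
#' * `one_sided` — the binary exceedance indicator `1{p > threshold}` for the
#'   logistic GLME.
#'
#' Time enters the fits in days (`time_day = time_min / 1440`) for optimizer
#' stability; fitted slopes are reported on both scales.
#'
#' @param records Percentile records with `patient_id`, `diagnosis`,
#'   `time_min`, `percentile` (typically [segmented_percentiles()] output).
#' @param metric `"quadratic"` or `"one_sided"`.
#' @param time_cap_min Drop observations with `time_min` beyond this cap.
#' @param eps Clamp width for the logit transform.
#' @param threshold Exceedance threshold for the one-sided response.
#' @return Data frame `patient_id, diagnosis (factor), time_min, time_day,
#'   response`, with attributes `metric` and `n_dropped`.
#' @export
build_observations <- function(records, metric = c("quadratic", "one_sided"),
                               time_cap_min = 8000, eps = 1e-6,
                               threshold = 0.9) {
  metric <- match.arg(metric)
  keep <- records$time_min <= time_cap_min
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("build_observations: dropped %d observations beyond %g min",
                    n_dropped, time_cap_min))
  }
  d <- records[keep, , drop = FALSE]
  p <- d$percentile
  response <- if (metric == "quadratic") {
    x <- pmin(pmax(4 * (p - 0.5)^2, eps), 1 - eps)
    log(x / (1 - x))
  } else {
    as.integer(p > threshold)
  }
  levs <- intersect(diagnosis_groups(), unique(d$diagnosis))
  out <- data.frame(patient_id = factor(d$patient_id),
                    diagnosis = factor(d$diagnosis, levels = levs),
                    time_min = d$time_min,
                    time_day = d$time_min / 1440,
                    response = response)
  attr(out, "metric") <- metric
  attr(out, "n_dropped") <- n_dropped
  out
}

.new_mixed_result <- function(fit, backend, method, metric, converged,
                              message = NA_character_) {
  res <- list(fit = fit, backend = backend, method = method, metric = metric,
              converged = converged, message = message,
              fixed = NULL, time_per_day = NA_real_, time_per_min = NA_real_,
              vcov_fixed = NULL, varcorr = NULL, sigma = NA_real_)
  if (!is.null(fit)) {
    beta <- if (backend == "nlme") nlme::fixef(fit) else lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    grp <- grep("^diagnosis", names(beta))
    res$fixed <- beta[grp]
    names(res$fixed) <- sub("^diagnosis", "", names(res$fixed))
    res$time_per_day <- unname(beta["time_day"])
    res$time_per_min <- res$time_per_day / 1440
    res$vcov_fixed <- vc
    res$coef_names <- names(beta)
    res$varcorr <- if (backend == "nlme") nlme::VarCorr(fit) else
      lme4::VarCorr(fit)
    res$sigma <- if (backend == "nlme") fit$sigma else NA_real_
  }
  class(res) <- "si_mixed_model"
  res
}

#' @export
print.si_mixed_model <- function(x, ...) {
  cat(sprintf("si_mixed_model (%s, %s, %s response)%s\n", x$backend, x$method,
              x$metric, if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$fixed)) {
    print(round(x$fixed, 4))
    cat(sprintf("Time: %.6g per minute (%.4f per day)\n",
                x$time_per_min, x$time_per_day))
  }
  invisible(x)
}

#' Linear mixed model for the logit-transformed quadratic penalty
#'
#' Fits, by REML, the cell-means longitudinal model
#' `y_ij = sum_k beta_k d_k(i) + beta_T t_ij + b_0i + b_1i t_ij + e_ij`:
#' six diagnosis-group fixed intercepts (no global intercept), a common fixed
#' time slope, and correlated per-patient random intercept and slope. The six
#' group coefficients estimate each group's (transformed) variability at
#' admission; the time coefficient its common drift.
#'
#' @param obs Observation table from [build_observations()] with the
#'   quadratic response.
#' @param method `"REML"` (headline fits) or `"ML"` (for LR comparisons).
#' @return An `si_mixed_model`; non-convergence is flagged via `converged`,
#'   never silently worked around.
#' @export
fit_lme_quadratic <- function(obs, method = "REML") {
  fit <- tryCatch(
    nlme::lme(response ~ 0 + diagnosis + time_day,
              random = ~ 1 + time_day | patient_id,
              data = obs, method = method,
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         opt = "optim")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(.new_mixed_result(NULL, "nlme", method, "quadratic", FALSE,
                             conditionMessage(fit)))
  }
  .new_mixed_result(fit, "nlme", method, "quadratic", TRUE)
}

#' Logistic-binomial generalized linear mixed model for exceedance
#'
#' Fits the per-hour exceedance indicator with a logistic link and binomial
#' family by Laplace-approximated maximum likelihood: the same cell-means
#' fixed structure and per-patient random intercept + slope as the LME, with
#' no residual term.
#'
#' @param obs Observation table from [build_observations()] with the
#'   one-sided response.
#' @return An `si_mixed_model`. Complete separation or optimizer failure is
#'   reported through `converged`/`message`.
#' @export
fit_glme_onesided <- function(obs) {
  if (length(unique(obs$response)) < 2) {
    stop("both outcome classes must be present to fit the GLME",
         call. = FALSE)
  }
  fit <- tryCatch(
    lme4::glmer(response ~ 0 + diagnosis + time_day +
                  (1 + time_day | patient_id),
                data = obs, family = stats::binomial(), nAGQ = 1L,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(.new_mixed_result(NULL, "lme4", "Laplace", "one_sided", FALSE,
                             conditionMessage(fit)))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- length(msgs) == 0 && max(abs(lme4::fixef(fit))) < 30
  .new_mixed_result(fit, "lme4", "Laplace", "one_sided", converged,
                    if (length(msgs)) paste(msgs, collapse = "; ")
                    else NA_character_)
}

.lr_row <- function(test, ll1, ll0, df) {
  stat <- max(0, 2 * (ll1 - ll0))
  data.frame(test = test, statistic = stat, df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio tests for the random-effects structure
#'
#' Tests, by ML likelihood ratios, whether the per-patient random intercept
#' (vs no random effects) and the per-patient random slope (vs intercept
#' only) are needed. Both null hypotheses sit on the variance boundary, so
#' the naive chi-square reference is conservative; this is recorded in the
#' `boundary_note` attribute rather than corrected.
#'
#' @param obs Observation table from [build_observations()].
#' @param metric Which model family to test; defaults to the table's metric.
#' @return Data frame with rows `random_intercept` (df 1) and `random_slope`
#'   (df 2: slope variance + covariance).
#' @export
lr_test_random_structure <- function(obs, metric = attr(obs, "metric")) {
  metric <- match.arg(metric, c("quadratic", "one_sided"))
  if (metric == "quadratic") {
    m0 <- nlme::gls(response ~ 0 + diagnosis + time_day, data = obs,
                    method = "ML")
    m1 <- nlme::lme(response ~ 0 + diagnosis + time_day,
                    random = ~ 1 | patient_id, data = obs, method = "ML")
    m2 <- nlme::lme(response ~ 0 + diagnosis + time_day,
                    random = ~ 1 + time_day | patient_id, data = obs,
                    method = "ML",
                    control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                               opt = "optim"))
  } else {
    m0 <- stats::glm(response ~ 0 + diagnosis + time_day, data = obs,
                     family = stats::binomial())
    ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
    m1 <- lme4::glmer(response ~ 0 + diagnosis + time_day + (1 | patient_id),
                      data = obs, family = stats::binomial(), control = ctrl)
    m2 <- lme4::glmer(response ~ 0 + diagnosis + time_day +
                        (1 + time_day | patient_id),
                      data = obs, family = stats::binomial(), control = ctrl)
  }
  ll <- vapply(list(m0, m1, m2), function(m) as.numeric(stats::logLik(m)), 0)
  out <- rbind(.lr_row("random_intercept", ll[2], ll[1], 1L),
               .lr_row("random_slope", ll[3], ll[2], 2L))
  attr(out, "boundary_note") <-
    "variance-boundary null: naive chi-square p-values are conservative"
  out
}

#' Test the need for AR(1) within-patient residual correlation
#'
#' Compares, by ML likelihood ratio, the quadratic-penalty LME with and
#' without a continuous-time AR(1) correlation of within-patient errors
#' (`corCAR1` over minutes). If the joint AR(1) fit fails numerically, falls
#' back to a tagged Ljung-Box portmanteau test on within-patient residuals
#' of the base fit.
#'
#' @param obs Observation table (quadratic response).
#' @return List `statistic, df, p_value, method` with method `"lr_car1"` or
#'   `"ljung_box_fallback"`. Patients with fewer than 3 observations are
#'   excluded (with a message) since they carry no correlation information.
#' @export
test_ar1_necessity <- function(obs) {
  n_per <- table(obs$patient_id)
  short <- names(n_per)[n_per < 3]
  if (length(short) > 0) {
    message(sprintf("test_ar1_necessity: excluding %d patients with < 3 observations",
                    length(short)))
    obs <- droplevels(obs[!(obs$patient_id %in% short), , drop = FALSE])
  }
  base <- nlme::lme(response ~ 0 + diagnosis + time_day,
                    random = ~ 1 + time_day | patient_id, data = obs,
                    method = "ML",
                    control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                               opt = "optim"))
  ar1 <- tryCatch(
    stats::update(base,
                  correlation = nlme::corCAR1(form = ~ time_min | patient_id)),
    error = function(e) e)
  if (!inherits(ar1, "error")) {
    stat <- max(0, 2 * (as.numeric(stats::logLik(ar1)) -
                          as.numeric(stats::logLik(base))))
    return(list(statistic = stat, df = 1L,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                method = "lr_car1"))
  }
  ## fallback: pooled Ljung-Box (lag 1) on within-patient residual series
  res <- stats::resid(base, type = "normalized")
  stats_lb <- unlist(lapply(split(res, obs$patient_id), function(r) {
    if (length(r) < 3) return(NULL)
    stats::Box.test(r, lag = 1, type = "Ljung-Box")$statistic
  }))
  stat <- sum(stats_lb)
  df <- length(stats_lb)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       method = "ljung_box_fallback")
}

#' Joint test of the Time-by-Diagnosis fixed-effect interaction
#'
#' ML likelihood-ratio test (5 df) of group-specific time slopes against the
#' common-slope model. Non-rejection licenses the cell-means model with a
#' single time coefficient.
#'
#' @param obs Observation table from [build_observations()].
#' @param metric Model family; defaults to the table's metric.
#' @return List `statistic, df, p_value`.
#' @export
test_time_diagnosis_interaction <- function(obs,
                                            metric = attr(obs, "metric")) {
  metric <- match.arg(metric, c("quadratic", "one_sided"))
  df_int <- nlevels(obs$diagnosis) - 1L
  if (metric == "quadratic") {
    ctrl <- nlme::lmeControl(maxIter = 100, msMaxIter = 100, opt = "optim")
    reduced <- nlme::lme(response ~ 0 + diagnosis + time_day,
                         random = ~ 1 + time_day | patient_id, data = obs,
                         method = "ML", control = ctrl)
    full <- nlme::lme(response ~ 0 + diagnosis + diagnosis:time_day,
                      random = ~ 1 + time_day | patient_id, data = obs,
                      method = "ML", control = ctrl)
  } else {
    ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
    reduced <- lme4::glmer(response ~ 0 + diagnosis + time_day +
                             (1 + time_day | patient_id), data = obs,
                           family = stats::binomial(), control = ctrl)
    full <- lme4::glmer(response ~ 0 + diagnosis + diagnosis:time_day +
                          (1 + time_day | patient_id), data = obs,
                        family = stats::binomial(), control = ctrl)
  }
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  list(statistic = stat, df = df_int,
       p_value = stats::pchisq(stat, df_int, lower.tail = FALSE))
}

#' Tukey HSD pairwise contrasts of the diagnosis-group coefficients
#'
#' All 15 pairwise differences of the six cell-means diagnosis coefficients,
#' with single-step family-wise-adjusted p-values from the joint normal
#' distribution of the contrasts (Tukey's honestly significant differences,
#' via the multivariate-normal machinery of `multcomp`).
#'
#' @param result A converged `si_mixed_model`.
#' @return Data frame `comparison, estimate, se, z, p_raw, p_adjusted` with
#'   one row per unordered group pair (later group minus earlier group in
#'   canonical order).
#' @export
tukey_hsd <- function(result) {
  if (!inherits(result, "si_mixed_model") || is.null(result$fit)) {
    stop("tukey_hsd needs a converged si_mixed_model", call. = FALSE)
  }
  beta <- if (result$backend == "nlme") nlme::fixef(result$fit) else
    lme4::fixef(result$fit)
  vc <- as.matrix(stats::vcov(result$fit))
  dimnames(vc) <- list(names(beta), names(beta))
  grp_names <- grep("^diagnosis", names(beta), value = TRUE)
  groups <- sub("^diagnosis", "", grp_names)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  K <- matrix(0, ncol(pairs), length(beta),
              dimnames = list(NULL, names(beta)))
  labels <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    K[j, grp_names[b]] <- 1
    K[j, grp_names[a]] <- -1
    labels[j] <- paste(groups[b], "-", groups[a])
  }
  rownames(K) <- labels
  gh <- multcomp::glht(multcomp::parm(beta, vc), linfct = K)
  sm <- summary(gh)  # single-step (Tukey-type) adjustment by default
  est <- as.numeric(sm$test$coefficients)
  se <- as.numeric(sm$test$sigma)
  z <- as.numeric(sm$test$tstat)
  data.frame(comparison = labels, estimate = est, se = se, z = z,
             p_raw = 2 * stats::pnorm(-abs(z)),
             p_adjusted = as.numeric(sm$test$pvalues),
             stringsAsFactors = FALSE)
}

#' Time coefficient per day of stay
#'
#' Converts the fitted per-minute time coefficient to the per-day scale
#' (multiplication by 1440 minutes/day), the scale on which daily evolution
#' is reported.
#'
#' @param result An `si_mixed_model`, or a bare per-minute coefficient.
#' @return The per-day slope.
#' @export
time_coefficient_per_day <- function(result) {
  beta_min <- if (inherits(result, "si_mixed_model")) result$time_per_min
  else as.numeric(result)
  beta_min * 1440
}
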