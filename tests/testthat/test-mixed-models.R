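test_that("observation builder transforms, thresholds, and caps correctly", {
  p <- c(0.5, 0.95, 0.9, 0.2)
  recs <- manual_records(p, t = c(60, 120, 7980, 8100))
  expect_message(
    obs_q <- build_observations(recs, "quadratic"), "dropped 1")
  expect_identical(nrow(obs_q), 3L)
  expect_identical(attr(obs_q, "n_dropped"), 1L)
  # p = 0.5 clamps to eps: the most negative attainable response
  expect_equal(obs_q$response[1], qlogis(1e-6), tolerance = 1e-9)
  expect_equal(obs_q$response[2], qlogis(4 * (0.95 - 0.5)^2), tolerance = 1e-9)
  obs_o <- suppressMessages(build_observations(recs, "one_sided"))
  expect_identical(obs_o$response, c(0L, 1L, 0L))  # p = 0.9 exactly: not exceed
  # retained count equals a brute-force census of the cap
  set.seed(41)
  recs2 <- manual_records(runif(500), t = sample(1:16000, 500))
  obs2 <- suppressMessages(build_observations(recs2, "one_sided"))
  expect_identical(nrow(obs2), sum(recs2$time_min <= 8000))
})

test_that("cell-means LME recovers coefficients in the near-noiseless limit", {
  beta <- c(NOpC = -0.5, OpC = -0.45, NOpG = -1.0, OpG = -0.7,
            NOpO = -0.74, OpO = -0.85)
  obs <- simulate_lme_data(n_per_group = 4, hours = 30, beta = beta,
                           beta_t_day = -0.18, sd_b0 = 0, sd_b1 = 0,
                           sd_e = 1e-6, seed = 2)
  fit <- fit_lme_quadratic(obs)
  expect_true(fit$converged)
  expect_equal(fit$fixed[names(beta)], beta, tolerance = 1e-3)
  expect_equal(fit$time_per_day, -0.18, tolerance = 1e-3)
  # cell-means invariant: group coefficient = group mean response at t = 0
})

test_that("LME slope estimates cover the truth at realistic noise", {
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    obs <- simulate_lme_data(n_per_group = 10, hours = 40,
                             beta_t_day = -0.18, seed = 100 + r)
    fit <- fit_lme_quadratic(obs)
    expect_true(fit$converged)
    se <- sqrt(diag(fit$vcov_fixed))[["time_day"]]
    ci <- fit$time_per_day + c(-1.96, 1.96) * se
    if (ci[1] <= -0.18 && -0.18 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 2L)
})

test_that("LME estimates are invariant to patient order", {
  obs <- simulate_lme_data(n_per_group = 5, hours = 30, seed = 3)
  fit1 <- fit_lme_quadratic(obs)
  set.seed(4)
  perm <- obs[sample(nrow(obs)), ]
  attr(perm, "metric") <- "quadratic"
  fit2 <- fit_lme_quadratic(perm)
  expect_equal(fit1$fixed, fit2$fixed, tolerance = 1e-8)
  expect_equal(fit1$time_per_day, fit2$time_per_day, tolerance = 1e-8)
})

test_that("covariate-free GLME intercept matches the closed-form logit", {
  set.seed(21)
  n_pat <- 150; n_obs <- 40
  obs <- data.frame(
    patient_id = factor(rep(sprintf("p%03d", 1:n_pat), each = n_obs)),
    diagnosis = factor("NOpO", levels = "NOpO"),
    time_min = rep(seq(60, by = 60, length.out = n_obs), n_pat))
  obs$time_day <- obs$time_min / 1440
  obs$response <- rbinom(nrow(obs), 1, 0.10)
  attr(obs, "metric") <- "one_sided"
  fit <- suppressMessages(lme4::glmer(
    response ~ 1 + (1 | patient_id), data = obs, family = binomial(),
    control = lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)))
  expect_equal(unname(lme4::fixef(fit)[1]), qlogis(0.10), tolerance = 0.1)
})

test_that("GLME recovers a negative time slope from simulated exceedance", {
  obs <- simulate_glme_data(n_per_group = 15, hours = 60,
                            beta_t_day = -0.2, seed = 31)
  fit <- fit_glme_onesided(obs)
  expect_false(is.null(fit$fit))
  expect_lt(fit$time_per_day, 0)
  expect_equal(fit$time_per_min, fit$time_per_day / 1440, tolerance = 1e-12)
  # single-class response is rejected up front
  obs0 <- obs; obs0$response <- 0L
  expect_error(fit_glme_onesided(obs0), "both outcome classes")
})

test_that("random-structure LR tests detect strong random effects and stay nonnegative", {
  obs <- simulate_lme_data(n_per_group = 10, hours = 40,
                           sd_b0 = 0.8, sd_b1 = 0.3, sd_e = 0.4, seed = 51)
  lr <- lr_test_random_structure(obs)
  expect_identical(lr$test, c("random_intercept", "random_slope"))
  expect_true(all(lr$statistic >= 0))
  expect_true(all(lr$p_value >= 0 & lr$p_value <= 1))
  expect_lt(lr$p_value[1], 1e-6)  # strong intercept variance
  expect_lt(lr$p_value[2], 1e-6)  # strong slope variance
  expect_match(attr(lr, "boundary_note"), "conservative")
})

test_that("random-slope LR test is conservative when the slope variance is zero", {
  rejections <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    obs <- simulate_lme_data(n_per_group = 8, hours = 25,
                             sd_b0 = 0.5, sd_b1 = 0, sd_e = 0.5,
                             seed = 200 + r)
    lr <- lr_test_random_structure(obs)
    if (lr$p_value[2] < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)  # at most ~5% nominal; boundary makes it fewer
})

test_that("AR(1) necessity test separates white and autocorrelated residuals", {
  obs_white <- simulate_lme_data(n_per_group = 10, hours = 40,
                                 sd_b0 = 0.3, sd_b1 = 0.02, sd_e = 0.5,
                                 seed = 61)
  res_w <- test_ar1_necessity(obs_white)
  expect_true(res_w$method %in% c("lr_car1", "ljung_box_fallback"))
  expect_gt(res_w$p_value, 0.001)
  # inject strong AR(1) within-patient errors
  obs_ar <- obs_white
  set.seed(62)
  for (id in levels(obs_ar$patient_id)) {
    idx <- which(obs_ar$patient_id == id)
    e <- as.numeric(arima.sim(list(ar = 0.8), n = length(idx), sd = 0.5))
    obs_ar$response[idx] <- obs_ar$response[idx] + e
  }
  res_a <- test_ar1_necessity(obs_ar)
  expect_lt(res_a$p_value, 1e-4)
  # patient relabeling leaves the statistic unchanged
  obs_rl <- obs_white
  levels(obs_rl$patient_id) <- rev(levels(obs_rl$patient_id))
  res_rl <- test_ar1_necessity(obs_rl)
  expect_equal(res_rl$statistic, res_w$statistic, tolerance = 1e-6)
})

test_that("time-by-diagnosis interaction test flags only heterogeneous slopes", {
  obs_common <- simulate_lme_data(n_per_group = 10, hours = 40, seed = 71)
  res_c <- test_time_diagnosis_interaction(obs_common)
  expect_identical(res_c$df, 5L)
  expect_true(res_c$p_value >= 0 && res_c$p_value <= 1)
  expect_gt(res_c$p_value, 0.01)
  # one group's slope strongly different
  obs_het <- obs_common
  idx <- obs_het$diagnosis == "OpC"
  obs_het$response[idx] <- obs_het$response[idx] - 1.2 * obs_het$time_day[idx]
  attr(obs_het, "metric") <- "quadratic"
  res_h <- test_time_diagnosis_interaction(obs_het)
  expect_lt(res_h$p_value, 0.01)
})

test_that("Tukey HSD emits all 15 pairwise contrasts with dominance bounds", {
  obs <- simulate_lme_data(n_per_group = 8, hours = 30, seed = 81)
  fit <- fit_lme_quadratic(obs)
  tk <- tukey_hsd(fit)
  expect_identical(nrow(tk), 15L)
  expect_identical(anyDuplicated(tk$comparison), 0L)
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))
  # single-step adjusted p is bounded by the Bonferroni-adjusted raw p
  expect_true(all(tk$p_adjusted <= pmin(1, 15 * tk$p_raw) + 1e-8))
  expect_true(all(tk$p_adjusted >= tk$p_raw - 1e-8))
  # contrast estimates are the plain coefficient differences
  est_oracle <- fit$fixed[["OpC"]] - fit$fixed[["NOpC"]]
  expect_equal(tk$estimate[tk$comparison == "OpC - NOpC"], est_oracle,
               tolerance = 1e-10)
})

test_that("Tukey HSD rarely rejects when all groups are simulated equal", {
  clean <- 0L
  n_rep <- 10L
  beta_eq <- setNames(rep(-0.7, 6), diagnosis_groups())
  for (r in seq_len(n_rep)) {
    obs <- simulate_lme_data(n_per_group = 8, hours = 25, beta = beta_eq,
                             seed = 300 + r)
    tk <- tukey_hsd(fit_lme_quadratic(obs))
    if (min(tk$p_adjusted) > 0.05) clean <- clean + 1L
  }
  expect_gte(clean, 8L)
})

test_that("per-day conversion is exact multiplication by 1440", {
  expect_identical(time_coefficient_per_day(0), 0)
  expect_equal(time_coefficient_per_day(-2e-4), -0.288, tolerance = 1e-12)
  res <- structure(list(time_per_min = -1e-4), class = "si_mixed_model")
  expect_equal(time_coefficient_per_day(res), -0.144, tolerance = 1e-12)
})
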