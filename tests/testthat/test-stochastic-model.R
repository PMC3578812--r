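test_that("transition extraction counts pairs within, never across, patients", {
  lens <- c(5L, 2L, 24L)
  trajs <- lapply(seq_along(lens), function(i) {
    manual_trajectory(exp(rnorm(lens[i])), id = paste0("p", i))
  })
  co <- structure(list(trajectories = trajs), class = "si_cohort")
  pairs <- extract_transitions(co)
  expect_identical(nrow(pairs), sum(lens - 1L))  # 4 + 1 + 23 = 28
  # no pair spans patients: every (from, to) is a consecutive within-patient pair
  for (i in seq_along(lens)) {
    sub <- pairs[pairs$patient_id == paste0("p", i), ]
    expect_equal(sub$si_from, trajs[[i]]$si_values[-lens[i]])
    expect_equal(sub$si_to, trajs[[i]]$si_values[-1])
  }
})

test_that("a cohort of H observations over P patients yields H - P pairs", {
  co <- tiny_cohort(seed = 17)
  H <- sum(vapply(co$trajectories, function(tr) length(tr$si_values), 0L))
  P <- length(co$trajectories)
  expect_identical(nrow(extract_transitions(co)), H - P)
  # length-1 trajectories contribute zero pairs, silently
  co$trajectories <- c(co$trajectories,
                       list(manual_trajectory(2.5, id = "solo")))
  expect_identical(nrow(extract_transitions(co)), H - P)
})

test_that("degenerate spread falls back to a positive bandwidth", {
  pairs <- data.frame(si_from = c(2, 2), si_to = c(3, 3))
  m <- fit_stochastic_model(pairs)
  expect_true(all(m$bandwidth_u > 0))
  expect_true(all(m$bandwidth_v > 0))
  expect_equal(conditional_cdf(m, 2, 3), 0.5, tolerance = 1e-12)
})

test_that("fitting rejects undersized or nonpositive input", {
  expect_error(fit_stochastic_model(data.frame(si_from = 1, si_to = 1)),
               "at least 2")
  expect_error(fit_stochastic_model(data.frame(si_from = c(1, -1),
                                               si_to = c(1, 2))),
               "positive")
})

test_that("refitting on permuted pairs gives identical conditional CDFs", {
  co <- tiny_cohort(seed = 23, n_per_group = 1)
  pairs <- extract_transitions(co)
  set.seed(4)
  perm <- pairs[sample(nrow(pairs)), ]
  m1 <- fit_stochastic_model(pairs)
  m2 <- fit_stochastic_model(perm)
  xs <- c(0.8, 2, 5)
  ys <- c(0.5, 2.5, 8)
  for (x in xs) expect_equal(conditional_cdf(m1, x, ys),
                             conditional_cdf(m2, x, ys), tolerance = 1e-12)
})

test_that("joint density integrates to one over the plane", {
  m <- tiny_model(seed = 29, n_per_group = 1, los_med_h = 30)
  # mixture of bivariate Gaussians on (log x, log y); integrate on a wide
  # log-scale grid by the trapezoid rule in each dimension
  gu <- seq(min(m$centres_u) - 8 * max(m$bandwidth_u),
            max(m$centres_u) + 8 * max(m$bandwidth_u), length.out = 401)
  gv <- seq(min(m$centres_v) - 8 * max(m$bandwidth_v),
            max(m$centres_v) + 8 * max(m$bandwidth_v), length.out = 401)
  dens <- matrix(0, length(gu), length(gv))
  for (i in seq_len(m$n_transitions)) {
    dens <- dens + outer(dnorm(gu, m$centres_u[i], m$bandwidth_u[i]),
                         dnorm(gv, m$centres_v[i], m$bandwidth_v[i]))
  }
  dens <- dens / m$n_transitions
  du <- diff(gu[1:2]); dv <- diff(gv[1:2])
  total <- sum(dens) * du * dv
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("single-centre symmetry and tail limits of the conditional CDF", {
  pairs <- data.frame(si_from = c(2, 2), si_to = c(3, 3))
  m <- fit_stochastic_model(pairs)
  expect_equal(conditional_cdf(m, 2, 3), 0.5, tolerance = 1e-12)
  m2 <- tiny_model(seed = 37, n_per_group = 1)
  expect_lte(conditional_cdf(m2, 3, 1e-8), 1e-6)
  expect_gte(conditional_cdf(m2, 3, 1e8), 1 - 1e-6)
  expect_error(conditional_cdf(m2, -1, 2), "positive")
  expect_error(conditional_cdf(m2, 2, -1), "positive")
})

test_that("conditional CDF equals quadrature of the conditional density", {
  m <- tiny_model(seed = 43, n_per_group = 1, los_med_h = 30)
  set.seed(6)
  for (rep in 1:100) {
    x <- exp(runif(1, min(m$centres_u), max(m$centres_u)))
    y <- exp(runif(1, min(m$centres_v) - 1, max(m$centres_v) + 1))
    num <- integrate(function(t) conditional_pdf(m, x, t),
                     lower = 0, upper = y,
                     rel.tol = 1e-10, abs.tol = 1e-10,
                     subdivisions = 400L)$value
    expect_equal(conditional_cdf(m, x, y), num, tolerance = 1e-6)
  }
})

test_that("conditional CDF is monotone in si_to and weights sum to one", {
  m <- tiny_model(seed = 47, n_per_group = 2)
  set.seed(8)
  ys <- sort(exp(runif(1000, min(m$centres_v) - 1, max(m$centres_v) + 1)))
  for (rep in 1:100) {
    x <- exp(runif(1, min(m$centres_u) - 1, max(m$centres_u) + 1))
    p <- batch_percentiles(m, rep(x, length(ys)), ys)
    expect_true(all(diff(p) >= -1e-12))
    w <- sivar:::conditional_weights(m, x)
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("quantiles invert the CDF, are monotone, and match grid inversion", {
  m <- tiny_model(seed = 53, n_per_group = 1)
  x <- 2.5
  qs <- c(0.25, 0.5, 0.75, 0.9)
  ys <- conditional_quantile(m, x, qs)
  expect_true(all(diff(ys) > 0))
  for (i in seq_along(qs)) {
    expect_equal(conditional_cdf(m, x, ys[i]), qs[i], tolerance = 1e-6)
  }
  # brute-force inversion on a dense log grid
  grid <- seq(min(m$centres_v) - 6 * max(m$bandwidth_v),
              max(m$centres_v) + 6 * max(m$bandwidth_v), length.out = 1e5)
  cdf_grid <- batch_percentiles(m, rep(x, length(grid)), exp(grid))
  for (i in seq_along(qs)) {
    y_grid <- exp(grid[which.min(abs(cdf_grid - qs[i]))])
    expect_equal(ys[i], y_grid, tolerance = diff(grid[1:2]) * 2 + 1e-6)
  }
  expect_error(conditional_quantile(m, x, 0), "strictly between")
  expect_error(conditional_quantile(m, x, 1), "strictly between")
})

test_that("sample_next draws reproduce the conditional CDF and are positive", {
  m <- tiny_model(seed = 59, n_per_group = 1, los_med_h = 30)
  x <- 3
  set.seed(123)
  draws <- sample_next(m, rep(x, 1e4))
  expect_true(all(draws > 0))
  ks <- suppressWarnings(
    ks.test(draws, function(q) conditional_cdf(m, x, q)))
  expect_lt(unname(ks$statistic), 0.02)
  set.seed(77); d1 <- sample_next(m, c(2, 3))
  set.seed(77); d2 <- sample_next(m, c(2, 3))
  expect_identical(d1, d2)
})

test_that("batch percentiles agree with the scalar conditional CDF", {
  m <- tiny_model(seed = 61, n_per_group = 1)
  set.seed(9)
  xf <- exp(runif(50, min(m$centres_u), max(m$centres_u)))
  xt <- exp(runif(50, min(m$centres_v), max(m$centres_v)))
  batch <- batch_percentiles(m, xf, xt, chunk = 7L)
  scalar <- mapply(function(a, b) conditional_cdf(m, a, b), xf, xt)
  expect_equal(batch, unname(scalar), tolerance = 1e-12)
})

test_that("adaptive k-NN bandwidths still give a proper, monotone CDF", {
  co <- tiny_cohort(seed = 67, n_per_group = 1)
  m <- fit_stochastic_model(extract_transitions(co), bandwidth_rule = "knn")
  expect_true(all(m$bandwidth_u > 0))
  ys <- exp(seq(min(m$centres_v) - 1, max(m$centres_v) + 1, length.out = 500))
  p <- batch_percentiles(m, rep(2.5, length(ys)), ys)
  expect_true(all(diff(p) >= -1e-12))
  expect_lt(p[1], 0.05)
  expect_gt(p[length(p)], 0.95)
})

test_that("model serialization round-trips through the text format", {
  m <- tiny_model(seed = 71, n_per_group = 1)
  path <- tempfile(fileext = ".csv")
  write_stochastic_model(m, path)
  m2 <- read_stochastic_model(path)
  expect_identical(m2$n_transitions, m$n_transitions)
  expect_identical(m2$transform, m$transform)
  expect_identical(m2$bandwidth_rule, m$bandwidth_rule)
  expect_equal(conditional_cdf(m2, 2, c(1, 3, 9)),
               conditional_cdf(m, 2, c(1, 3, 9)), tolerance = 1e-12)
})
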