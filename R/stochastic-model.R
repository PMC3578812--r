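#' Extract hourly SI transitions from a cohort
#'
#' One transition pair per consecutive hour within a patient; no pair spans
#' patients, so a trajectory of length L contributes L - 1 pairs and a cohort
#' totalling H hourly observations over P patients contributes H - P pairs.
#'
#' @param cohort An `si_cohort`.
#' @return Data frame with columns `si_from`, `si_to`, `patient_id`,
#'   `time_min` (minutes of the *from* observation).
#' @export
extract_transitions <- function(cohort) {
  out <- lapply(cohort$trajectories, function(tr) {
    n <- length(tr$si_values)
    if (n < 2) return(NULL)
    data.frame(si_from = tr$si_values[-n],
               si_to = tr$si_values[-1],
               patient_id = tr$patient_id,
               time_min = tr$times_min[-n],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(si_from = numeric(), si_to = numeric(),
                      patient_id = character(), time_min = numeric())
  }
  rownames(out) <- NULL
  out
}

## Silverman's rule of thumb in one dimension; fall back to a positive width
## when the spread is degenerate so the CDF stays proper.
.silverman_bw <- function(x) {
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-3, 1e-2 * abs(mean(x)))
  bw
}

#' Fit the whole-cohort stochastic model of hourly SI transitions
#'
#' Places one bivariate Gaussian kernel on each observed transition
#' `(log SI_n, log SI_{n+1})`. Estimating on the log scale respects the
#' positive, right-skewed support of SI. The model is fitted on all patients,
#' all days pooled; querying it at a current SI value gives a proper mixture
#' distribution over next-hour SI (see [conditional_cdf()]).
#'
#' @param pairs Transition table from [extract_transitions()] (needs columns
#'   `si_from`, `si_to`; at least 2 rows, all values positive).
#' @param bandwidth_rule `"silverman"` (default): one global Silverman
#'   bandwidth per dimension. `"knn"`: the global widths are additionally
#'   scaled per centre by the distance to the k-th nearest neighbour in the
#'   current-SI coordinate (relative to its geometric mean), adapting the
#'   kernel width to local data density.
#' @param knn_k Neighbour count for the adaptive rule; default
#'   `ceiling(sqrt(n))`.
#' @return An `si_stochastic_model` with per-centre coordinates
#'   (`centres_u`, `centres_v` on the log scale) and per-centre bandwidths
#'   (`bandwidth_u`, `bandwidth_v`).
#' @export
fit_stochastic_model <- function(pairs, bandwidth_rule = c("silverman", "knn"),
                                 knn_k = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (!all(c("si_from", "si_to") %in% names(pairs))) {
    stop("pairs must have columns si_from and si_to", call. = FALSE)
  }
  if (nrow(pairs) < 2) {
    stop("need at least 2 transition pairs to fit the stochastic model",
         call. = FALSE)
  }
  if (any(pairs$si_from <= 0) || any(pairs$si_to <= 0)) {
    stop("all SI values must be strictly positive", call. = FALSE)
  }
  u <- log(pairs$si_from)
  v <- log(pairs$si_to)
  n <- length(u)
  h_u <- .silverman_bw(u)
  h_v <- .silverman_bw(v)
  scale_i <- rep(1, n)
  if (bandwidth_rule == "knn") {
    k <- if (is.null(knn_k)) ceiling(sqrt(n)) else as.integer(knn_k)
    k <- min(max(k, 1L), n - 1L)
    d_k <- vapply(seq_len(n), function(i) {
      sort(abs(u[-i] - u[i]), partial = k)[k]
    }, 0)
    d_k <- pmax(d_k, 1e-12)
    scale_i <- d_k / exp(mean(log(d_k)))
  }
  structure(
    list(centres_u = u, centres_v = v,
         bandwidth_u = h_u * scale_i, bandwidth_v = h_v * scale_i,
         n_transitions = n,
         transform = "log", bandwidth_rule = bandwidth_rule),
    class = "si_stochastic_model"
  )
}

assert_stochastic_model <- function(model) {
  if (!inherits(model, "si_stochastic_model")) {
    stop("model must be a fitted si_stochastic_model", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.si_stochastic_model <- function(x, ...) {
  cat(sprintf(
    "si_stochastic_model: %d transitions, %s transform, %s bandwidths (h_u ~ %.4g, h_v ~ %.4g)\n",
    x$n_transitions, x$transform, x$bandwidth_rule,
    stats::median(x$bandwidth_u), stats::median(x$bandwidth_v)))
  invisible(x)
}

## Mixture weights of the conditional distribution at one current-SI value.
## Log-space softmax avoids underflow far from the centres.
conditional_weights <- function(model, si_from) {
  lw <- stats::dnorm(log(si_from), model$centres_u, model$bandwidth_u,
                     log = TRUE)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Conditional distribution of next-hour SI
#'
#' `conditional_cdf()` evaluates `F(si_to | si_from)`, the probability that
#' next-hour SI falls at or below `si_to` given current SI `si_from`, under
#' the fitted kernel mixture:
#' `F = sum_i w_i(si_from) * Phi((log si_to - v_i) / h_v_i)` with weights
#' `w_i` proportional to the Gaussian kernel of `log si_from` at centre
#' `u_i`. It is nondecreasing in `si_to` with limits 0 and 1.
#'
#' @param model A fitted `si_stochastic_model`.
#' @param si_from Current SI value (positive scalar).
#' @param si_to Next-hour SI value(s), positive.
#' @return Probabilities in \[0, 1\], one per element of `si_to`.
#' @export
conditional_cdf <- function(model, si_from, si_to) {
  assert_stochastic_model(model)
  if (length(si_from) != 1 || !is.finite(si_from) || si_from <= 0) {
    stop("si_from must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(si_to)) || any(si_to <= 0)) {
    stop("si_to must be positive", call. = FALSE)
  }
  w <- conditional_weights(model, si_from)
  vapply(si_to, function(y) {
    sum(w * stats::pnorm((log(y) - model$centres_v) / model$bandwidth_v))
  }, 0)
}

#' Conditional density of next-hour SI
#'
#' Density counterpart of [conditional_cdf()] (lognormal mixture on the
#' original SI scale); mainly used for quadrature cross-checks and
#' distribution summaries.
#'
#' @inheritParams conditional_cdf
#' @return Nonnegative densities, one per element of `si_to`.
#' @export
conditional_pdf <- function(model, si_from, si_to) {
  assert_stochastic_model(model)
  w <- conditional_weights(model, si_from)
  vapply(si_to, function(y) {
    sum(w * stats::dlnorm(y, model$centres_v, model$bandwidth_v))
  }, 0)
}

#' Conditional quantile of next-hour SI
#'
#' Inverts [conditional_cdf()] by an expanding bracket followed by bisection
#' on the log-SI scale, to within 1e-10 on the probability scale. Under
#' Gaussian kernels the CDF is strictly increasing, so the root is unique.
#'
#' @inheritParams conditional_cdf
#' @param q Probability in (0, 1); may be a vector.
#' @return SI value(s) `y` with `conditional_cdf(model, si_from, y) = q`.
#' @export
conditional_quantile <- function(model, si_from, q) {
  assert_stochastic_model(model)
  if (any(q <= 0) || any(q >= 1)) {
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  }
  w <- conditional_weights(model, si_from)
  cdf_log <- function(t) {
    sum(w * stats::pnorm((t - model$centres_v) / model$bandwidth_v))
  }
  vapply(q, function(qq) {
    lo <- min(model$centres_v) - 6 * max(model$bandwidth_v)
    hi <- max(model$centres_v) + 6 * max(model$bandwidth_v)
    while (cdf_log(lo) > qq) lo <- lo - 5 * max(model$bandwidth_v)
    while (cdf_log(hi) < qq) hi <- hi + 5 * max(model$bandwidth_v)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      fm <- cdf_log(mid)
      if (abs(fm - qq) < 1e-10 || (hi - lo) < 1e-13) break
      if (fm < qq) lo <- mid else hi <- mid
    }
    exp(mid)
  }, 0)
}

#' Draw next-hour SI values from the fitted model
#'
#' For each current SI value, draws a mixture component with its conditional
#' weight, then a lognormal deviate from that component. Uses the current R
#' RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param model A fitted `si_stochastic_model`.
#' @param si_from Vector of current SI values (positive).
#' @return Positive next-hour SI draws, one per element of `si_from`.
#' @export
sample_next <- function(model, si_from) {
  assert_stochastic_model(model)
  if (any(si_from <= 0)) stop("si_from must be positive", call. = FALSE)
  comp <- vapply(si_from, function(x) {
    sample.int(model$n_transitions, 1L, prob = conditional_weights(model, x))
  }, 0L)
  exp(stats::rnorm(length(comp), model$centres_v[comp], model$bandwidth_v[comp]))
}

#' Batch percentile evaluation for many transitions
#'
#' Vectorised, chunked evaluation of
#' `conditional_cdf(model, si_from[j], si_to[j])` over paired vectors;
#' identical results to the scalar path but orders of magnitude faster on
#' cohort-sized inputs.
#'
#' @param model A fitted `si_stochastic_model`.
#' @param si_from,si_to Paired positive vectors of equal length.
#' @param chunk Number of transitions processed per block (memory control).
#' @return Numeric vector of percentiles in \[0, 1\].
#' @export
batch_percentiles <- function(model, si_from, si_to, chunk = 512L) {
  assert_stochastic_model(model)
  stopifnot(length(si_from) == length(si_to))
  if (any(si_from <= 0) || any(si_to <= 0)) {
    stop("SI values must be positive", call. = FALSE)
  }
  n <- length(si_from)
  out <- numeric(n)
  lx <- log(si_from)
  ly <- log(si_to)
  for (start in seq(1L, n, by = chunk)) {
    j <- start:min(start + chunk - 1L, n)
    ## log-kernel matrix: centres x queries
    lw <- -0.5 * (outer(model$centres_u, lx[j], "-") / model$bandwidth_u)^2 -
      log(model$bandwidth_u)
    lw <- sweep(lw, 2L, apply(lw, 2L, max), "-")
    w <- exp(lw)
    w <- sweep(w, 2L, colSums(w), "/")
    pz <- stats::pnorm(-outer(model$centres_v, ly[j], "-") / model$bandwidth_v)
    out[j] <- colSums(w * pz)
  }
  out
}

#' Serialize a fitted stochastic model to a self-describing text file
#'
#' Writes a CSV of kernel centres and bandwidths preceded by `#`-prefixed
#' metadata lines (transform, bandwidth rule, transition count).
#'
#' @param model A fitted `si_stochastic_model`.
#' @param path File path.
#' @return `write_stochastic_model()` returns `path` invisibly;
#'   `read_stochastic_model()` the reconstructed model.
#' @export
write_stochastic_model <- function(model, path) {
  assert_stochastic_model(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# si_stochastic_model",
    paste0("# transform: ", model$transform),
    paste0("# bandwidth_rule: ", model$bandwidth_rule),
    paste0("# n_transitions: ", model$n_transitions),
    "centre_u,centre_v,bandwidth_u,bandwidth_v"
  ), con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                     model$centres_u, model$centres_v,
                     model$bandwidth_u, model$bandwidth_v), con)
  invisible(path)
}

#' @rdname write_stochastic_model
#' @export
read_stochastic_model <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"), meta,
                                           value = TRUE))
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  structure(
    list(centres_u = tab$centre_u, centres_v = tab$centre_v,
         bandwidth_u = tab$bandwidth_u, bandwidth_v = tab$bandwidth_v,
         n_transitions = as.integer(get_meta("n_transitions")),
         transform = get_meta("transform"),
         bandwidth_rule = get_meta("bandwidth_rule")),
    class = "si_stochastic_model"
  )
}
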