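#' Decile coverage histogram of percentile records
#'
#' Tabulates percentiles into the ten bins \[0, 0.1), ..., \[0.9, 1.0\] (last
#' bin closed). Under perfect calibration every bin holds 10% of the
#' records; peaked ("kurtic") shapes mean the model's bands were too wide,
#' U-shapes that they were too narrow.
#'
#' @param records Percentile records (already segmented/filtered as desired).
#' @param day_label,diagnosis Optional filters; require a `day`/`diagnosis`
#'   column in `records` when used.
#' @return List with `day_label`, `diagnosis`, `counts` (10 integers), `n`.
#' @export
decile_histogram <- function(records, day_label = NULL, diagnosis = NULL) {
  if (!is.null(day_label)) records <- records[records$day == day_label, ]
  if (!is.null(diagnosis)) records <- records[records$diagnosis == diagnosis, ]
  p <- records$percentile
  counts <- integer(10)
  if (length(p) > 0) {
    idx <- pmin(floor(p * 10) + 1L, 10L)  # p = 1.0 lands in the last bin
    tb <- tabulate(idx, nbins = 10L)
    counts <- as.integer(tb)
  }
  list(day_label = if (is.null(day_label)) NA_character_ else day_label,
       diagnosis = if (is.null(diagnosis)) NA_character_ else diagnosis,
       counts = counts, n = sum(counts))
}

#' Chi-square uniformity statistic of a decile histogram
#'
#' Pearson chi-square with 9 degrees of freedom against equal expected
#' counts n/10 — a numeric summary of the coverage histogram's flatness.
#'
#' @param hist A histogram from [decile_histogram()].
#' @return List with `statistic`, `p_value`, `df`, and `small_sample`
#'   (`TRUE` when n < 50, where the chi-square approximation is doubtful;
#'   the statistic is still returned).
#' @export
uniformity_statistic <- function(hist) {
  n <- hist$n
  small <- n < 50
  if (small) {
    warning("uniformity_statistic: n < 50, chi-square approximation doubtful",
            call. = FALSE)
  }
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 9L,
                small_sample = TRUE))
  }
  expected <- n / 10
  stat <- sum((hist$counts - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 9, lower.tail = FALSE),
       df = 9L, small_sample = small)
}

#' Decile histogram table by day block and diagnosis group
#'
#' Convenience wrapper producing the full day-by-group grid of coverage
#' histograms from segmented percentile records.
#'
#' @param records Percentile records carrying `day` and `diagnosis` columns
#'   (e.g. from [segmented_percentiles()]).
#' @return Long data frame `day, diagnosis, bin_lo, bin_hi, count, n`.
#' @export
decile_histogram_table <- function(records) {
  combos <- unique(records[, c("day", "diagnosis")])
  combos <- combos[order(combos$day, combos$diagnosis), ]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    h <- decile_histogram(records, combos$day[i], combos$diagnosis[i])
    data.frame(day = combos$day[i], diagnosis = combos$diagnosis[i],
               bin_lo = seq(0, 0.9, by = 0.1), bin_hi = seq(0.1, 1, by = 0.1),
               count = h$counts, n = h$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segmented percentile records for a cohort
#'
#' Applies [segment_days()] per patient and returns the retained records with
#' a `day` column attached — the input expected by the descriptive surfaces.
#'
#' @inheritParams per_patient_day_scores
#' @return Data frame `patient_id, diagnosis, time_min, percentile, day`.
#' @export
segmented_percentiles <- function(cohort, model) {
  rows <- lapply(cohort$trajectories, function(tr) {
    recs <- percentile_series(model, tr)
    segs <- segment_days(recs, los_min = max(tr$times_min))
    if (length(segs) == 0) return(NULL)
    do.call(rbind, lapply(names(segs), function(lab) {
      cbind(segs[[lab]], day = lab, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), diagnosis = character(),
                      time_min = numeric(), percentile = numeric(),
                      day = character())
  }
  rownames(out) <- NULL
  out
}

#' LOWESS trend of a per-hour variability score against time of stay
#'
#' Locally weighted scatterplot smoothing of per-hour observations (default:
#' the squared percentile deviation that underlies the quadratic penalty)
#' against minute-precision time, one curve per diagnosis group, evaluated
#' on a uniform time grid.
#'
#' @param scores Data frame with columns `time_min`, `value`, `diagnosis`.
#' @param span Smoother span (fraction of points), default 2/3.
#' @param iter Robustness iterations, default 3.
#' @param grid_n Number of uniform grid points per group.
#' @param min_points Groups with fewer observations are skipped with a
#'   message.
#' @return Data frame `diagnosis, time_min, trend, span`.
#' @export
lowess_trend <- function(scores, span = 2 / 3, iter = 3L, grid_n = 100L,
                         min_points = 20L) {
  out <- lapply(split(scores, scores$diagnosis), function(d) {
    if (nrow(d) < min_points) {
      message(sprintf("lowess_trend: skipping group %s (%d < %d points)",
                      d$diagnosis[1], nrow(d), min_points))
      return(NULL)
    }
    sm <- stats::lowess(d$time_min, d$value, f = span, iter = iter)
    grid <- seq(min(d$time_min), max(d$time_min), length.out = grid_n)
    data.frame(diagnosis = d$diagnosis[1], time_min = grid,
               trend = stats::approx(sm$x, sm$y, xout = grid, rule = 2,
                                     ties = "ordered")$y,
               span = span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Distribution summaries of per-patient penalty scores
#'
#' Per (day block, diagnosis group, metric): mean, linear-interpolation
#' quartiles, and a Gaussian kernel density over the metric's support — the
#' numbers behind violin-plot style displays.
#'
#' @param penalties Table from [per_patient_day_scores()].
#' @param metrics Which penalty columns to summarise.
#' @param grid_n Density grid size.
#' @param min_cell Cells with fewer patients are flagged (`small_cell`);
#'   empty cells are omitted with a message.
#' @return List with `summary` (one row per cell) and `density` (long grid
#'   table `day, diagnosis, metric, x, density`).
#' @export
distribution_summary <- function(penalties, metrics = c("quadratic", "one_sided"),
                                 grid_n = 128L, min_cell = 3L) {
  cells <- unique(penalties[, c("day", "diagnosis")])
  sum_rows <- list()
  den_rows <- list()
  for (i in seq_len(nrow(cells))) {
    d <- penalties[penalties$day == cells$day[i] &
                     penalties$diagnosis == cells$diagnosis[i], ]
    for (m in metrics) {
      x <- d[[m]]
      if (length(x) == 0) {
        message(sprintf("distribution_summary: empty cell %s/%s/%s omitted",
                        cells$day[i], cells$diagnosis[i], m))
        next
      }
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        day = cells$day[i], diagnosis = cells$diagnosis[i], metric = m,
        n = length(x), mean = mean(x), q25 = qs[1], median = qs[2],
        q75 = qs[3], small_cell = length(x) < min_cell,
        stringsAsFactors = FALSE)
      if (length(x) >= 2 && stats::sd(x) > 0) {
        den <- stats::density(x, n = grid_n)
        den_rows[[length(den_rows) + 1L]] <- data.frame(
          day = cells$day[i], diagnosis = cells$diagnosis[i], metric = m,
          x = den$x, density = den$y, stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = {
    s <- do.call(rbind, sum_rows); if (!is.null(s)) rownames(s) <- NULL; s
  }, density = {
    s <- do.call(rbind, den_rows); if (!is.null(s)) rownames(s) <- NULL; s
  })
}
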