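#' Assemble per-condition metric time series from shape records
#'
#' Pools all objects from the same condition and timestamp across replicates
#' and fields of view (per-frame population statistics, not per-cell
#' trajectories), ordered by acquisition time, for each requested metric.
#'
#' @param records data.frame of shape records with at least `condition`,
#'   `timestamp_h` and the metric columns (`area_um2`, `circularity`,
#'   `major_axis_um`, `minor_axis_um`).
#' @param metrics metric names: any of `"area"`, `"circularity"`,
#'   `"major_axis"`, `"minor_axis"`.
#' @return nested list of class `metric_timeseries_set`:
#'   `series[[condition]][[metric]]` is a list with `timestamps_h`, `values`
#'   (list of per-timestamp value vectors), `mean`, `sd`, `n`.
#' @export
assemble_timeseries <- function(records,
                                metrics = c("area", "circularity",
                                            "major_axis", "minor_axis")) {
  col_map <- c(area = "area_um2", circularity = "circularity",
               major_axis = "major_axis_um", minor_axis = "minor_axis_um")
  bad <- setdiff(metrics, names(col_map))
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  stopifnot(all(c("condition", "timestamp_h") %in% names(records)))
  ts_all <- sort(unique(records$timestamp_h))
  series <- list()
  for (cond in unique(records$condition)) {
    rc <- records[records$condition == cond, ]
    series[[cond]] <- list()
    for (m in metrics) {
      vals <- split(rc[[col_map[[m]]]],
                    factor(rc$timestamp_h, levels = ts_all))
      series[[cond]][[m]] <- list(
        condition = cond, metric = m, timestamps_h = ts_all,
        values = unname(vals),
        mean = unname(vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                             numeric(1))),
        sd = unname(vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                           numeric(1))),
        n = unname(lengths(vals)))
    }
  }
  structure(list(series = series, timestamps_h = ts_all, metrics = metrics),
            class = "metric_timeseries_set")
}

#' Two-group F-test on metric values
#'
#' Default mode `"anova"`: the one-way two-group ANOVA F with degrees of
#' freedom `(1, n_a + n_b - 2)` — a test of equal means, identical to the
#' square of the pooled-variance two-sample t statistic (`F = t^2`, same
#' p-value). Mode `"variance"`: the variance-ratio F of
#' [stats::var.test()]. Both are shipped because "F-test" between two
#' measured distributions can mean either; the mode used is recorded in the
#' result.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param mode `"anova"` (default) or `"variance"`.
#' @return list: `F`, `p`, `df`, `mode`, `degenerate` (TRUE when the pooled
#'   within-group variance is 0: equal means then give `F = 0, p = 1`,
#'   unequal means `p = 0`).
#' @export
f_test <- function(a, b, mode = c("anova", "variance")) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  if (mode == "variance") {
    vt <- stats::var.test(a, b)
    return(list(F = unname(vt$statistic), p = vt$p.value,
                df = unname(vt$parameter), mode = mode, degenerate = FALSE))
  }
  df <- c(1, length(a) + length(b) - 2)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df[2]
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(F = 0, p = 1, df = df, mode = mode, degenerate = TRUE))
    return(list(F = Inf, p = 0, df = df, mode = mode, degenerate = TRUE))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  Fv <- t^2
  list(F = Fv, p = stats::pf(Fv, df[1], df[2], lower.tail = FALSE),
       df = df, mode = mode, degenerate = FALSE)
}

#' First divergence time of a p-value series
#'
#' The first schedule timestamp at which the between-condition test rejects
#' (`p < alpha`) and keeps rejecting for `persistence_k` consecutive
#' timestamps; `NA` ("never") if no such time exists. `persistence_k = 1`
#' reproduces a plain first-rejection rule; larger values guard against
#' isolated false positives.
#'
#' @param p_values per-timestamp p-values aligned with `timestamps_h`.
#' @param timestamps_h schedule timestamps (hours).
#' @param alpha significance level (default 0.05).
#' @param persistence_k consecutive rejections required (default 1).
#' @return divergence hour, or `NA_real_` for never.
#' @export
divergence_time <- function(p_values, timestamps_h, alpha = 0.05,
                            persistence_k = 1) {
  if (length(p_values) == 0) stop("empty p-value series")
  stopifnot(length(p_values) == length(timestamps_h), persistence_k >= 1)
  sig <- p_values < alpha
  sig[is.na(sig)] <- FALSE
  n <- length(sig)
  for (i in seq_len(n - persistence_k + 1)) {
    if (all(sig[i:(i + persistence_k - 1)])) return(timestamps_h[i])
  }
  NA_real_
}

#' Per-timestamp divergence analysis for one condition pair and metric
#'
#' Runs [f_test()] at every timestamp where both conditions have at least
#' two objects, then applies the [divergence_time()] rule.
#'
#' @param ts_set a `metric_timeseries_set` from [assemble_timeseries()].
#' @param cond_a,cond_b condition names.
#' @param metric metric name.
#' @param alpha,persistence_k see [divergence_time()].
#' @param mode F-test mode, see [f_test()].
#' @param p_adjust `"none"` (default, matching a plain per-timepoint rule) or
#'   any [stats::p.adjust()] method (e.g. `"holm"`) applied across
#'   timestamps before the divergence rule.
#' @return list of class `divergence_result`: `condition_pair`, `metric`,
#'   `timestamps_h`, `F`, `p`, `divergence_hour` (NA = never), `alpha`,
#'   `persistence_k`, `mode`, `p_adjust`.
#' @export
divergence_analysis <- function(ts_set, cond_a, cond_b, metric,
                                alpha = 0.05, persistence_k = 1,
                                mode = c("anova", "variance"),
                                p_adjust = "none") {
  mode <- match.arg(mode)
  sa <- ts_set$series[[cond_a]][[metric]]
  sb <- ts_set$series[[cond_b]][[metric]]
  if (is.null(sa) || is.null(sb))
    stop(sprintf("no series for %s vs %s on '%s'", cond_a, cond_b, metric))
  n_t <- length(sa$timestamps_h)
  Fv <- pv <- rep(NA_real_, n_t)
  for (i in seq_len(n_t)) {
    va <- sa$values[[i]]; vb <- sb$values[[i]]
    if (length(va) >= 2 && length(vb) >= 2) {
      r <- f_test(va, vb, mode = mode)
      Fv[i] <- r$F; pv[i] <- r$p
    }
  }
  p_used <- if (p_adjust == "none") pv else stats::p.adjust(pv, method = p_adjust)
  structure(list(condition_pair = c(cond_a, cond_b), metric = metric,
                 timestamps_h = sa$timestamps_h, F = Fv, p = p_used,
                 divergence_hour = divergence_time(p_used, sa$timestamps_h,
                                                   alpha, persistence_k),
                 alpha = alpha, persistence_k = persistence_k, mode = mode,
                 p_adjust = p_adjust),
            class = "divergence_result")
}

#' Divergence-hour table over condition pairs and metrics
#'
#' The summary layout of the study: rows are shape metrics, columns are
#' condition pairs, entries are the first hour at which the metric differs
#' between the two conditions (`NA` = never diverges).
#'
#' @param records shape-record data.frame (see [assemble_timeseries()]).
#' @param pairs list of 2-element character vectors of condition names.
#' @param metrics metric names.
#' @param ... passed to [divergence_analysis()].
#' @return data.frame: `metric` column plus one column per pair
#'   (`"condA/condB"`) of divergence hours.
#' @export
divergence_table <- function(records,
                             pairs = list(c("flat", "flat-osteo"),
                                          c("flat", "aligned"),
                                          c("random", "flat"),
                                          c("aligned", "random")),
                             metrics = c("area", "circularity",
                                         "major_axis", "minor_axis"),
                             ...) {
  ts_set <- assemble_timeseries(records, metrics)
  out <- data.frame(metric = metrics)
  for (pr in pairs) {
    col <- paste(pr, collapse = "/")
    out[[col]] <- vapply(metrics, function(m)
      divergence_analysis(ts_set, pr[1], pr[2], m, ...)$divergence_hour,
      numeric(1))
  }
  out
}

#' Mean-ratio dissimilarity trajectory between two condition series
#'
#' Per-timestamp ratio of the two condition means, plus a scalar summary of
#' how far the trajectory sits from unity (the median absolute log ratio).
#' Ratios with a zero denominator are `NaN` and flagged.
#'
#' @param series_a,series_b single-metric series (elements of a
#'   `metric_timeseries_set`, same metric, aligned timestamps).
#' @return list: `timestamps_h`, `ratio` (mean A / mean B), `summary`
#'   (median `|log(ratio)|`), `flagged` (logical, zero-denominator points).
#' @export
mean_ratio_trajectory <- function(series_a, series_b) {
  stopifnot(identical(series_a$timestamps_h, series_b$timestamps_h))
  denom <- series_b$mean
  flagged <- is.finite(denom) & denom == 0
  ratio <- series_a$mean / denom
  ratio[flagged] <- NaN
  ok <- is.finite(ratio) & ratio > 0
  list(timestamps_h = series_a$timestamps_h, ratio = ratio,
       summary = stats::median(abs(log(ratio[ok]))), flagged = flagged)
}
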