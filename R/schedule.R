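#' Build an acquisition schedule from imaging phases
#'
#' Long time-lapse experiments commonly switch cadence as the biology slows:
#' dense imaging while cells attach and spread, sparser imaging afterwards.
#' A schedule is defined by contiguous phases `(start_h, end_h, interval_h)`;
#' the timestamp grid of each phase runs from its start (exclusive, except for
#' the very first phase whose start is included) to its end (inclusive), so
#' phase boundaries are counted exactly once.
#'
#' Timestamps are computed on an integer grid per phase
#' (`start + k * interval`) rather than by accumulating floating-point steps,
#' so the grid is exactly reproducible and free of drift.
#'
#' @param phases list of numeric triples `c(start_h, end_h, interval_h)`, in
#'   hours. Phases must be contiguous (each start equals the previous end),
#'   strictly increasing, and each interval must divide its phase length.
#' @return An object of class `acquisition_schedule`: a list with `phases`
#'   and the ordered numeric vector `timestamps_h` (first timestamp is the
#'   start of the first phase).
#' @examples
#' sched <- make_schedule(default_phases())
#' range(sched$timestamps_h)   # 0 to 504 hours
#' length(sched$timestamps_h)  # 805 timepoints
#' @export
make_schedule <- function(phases) {
  if (!is.list(phases) || length(phases) == 0L)
    stop("`phases` must be a non-empty list of (start_h, end_h, interval_h) triples")
  ph <- lapply(phases, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || anyNA(p))
      stop("each phase must be a numeric triple (start_h, end_h, interval_h)")
    if (p[2] <= p[1]) stop("phase end must exceed phase start")
    if (p[3] <= 0) stop("phase interval must be positive")
    p
  })
  tol <- 1e-9
  for (i in seq_along(ph)) {
    if (i > 1L && abs(ph[[i]][1] - ph[[i - 1L]][2]) > tol)
      stop(sprintf("phases must be contiguous: phase %d starts at %g but phase %d ends at %g",
                   i, ph[[i]][1], i - 1L, ph[[i - 1L]][2]))
    n_steps <- (ph[[i]][2] - ph[[i]][1]) / ph[[i]][3]
    if (abs(n_steps - round(n_steps)) > 1e-6)
      stop(sprintf("interval %g does not divide phase %d length %g",
                   ph[[i]][3], i, ph[[i]][2] - ph[[i]][1]))
  }
  ts <- ph[[1L]][1]
  for (p in ph) {
    k <- round((p[2] - p[1]) / p[3])
    ts <- c(ts, p[1] + p[3] * seq_len(k))
  }
  stopifnot(all(diff(ts) > 0))
  structure(list(phases = ph, timestamps_h = ts), class = "acquisition_schedule")
}

#' Study-design imaging cadence
#'
#' The three-phase cadence of the 21-day experiment: every 10 min for the
#' first 6 h (attachment), every 15 min from 6 to 96 h (spreading), then every
#' 1 h from 96 to 504 h.
#'
#' @return list of phase triples suitable for [make_schedule()].
#' @export
default_phases <- function() {
  list(c(0, 6, 1 / 6), c(6, 96, 0.25), c(96, 504, 1))
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("acquisition schedule: %d timestamps, %g to %g h, %d phase(s)\n",
              length(x$timestamps_h), min(x$timestamps_h), max(x$timestamps_h),
              length(x$phases)))
  invisible(x)
}
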