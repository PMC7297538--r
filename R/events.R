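#' Extract feeding events (bouts) within a meal
#'
#' A feeding event is a maximal run of consecutive interaction samples; a
#' single sub-threshold sample terminates a run (no gap closure). An event
#' belongs to the meal when its first sample's timestamp lies in
#' `[meal$start_s, meal$end_s)`; assignment by event start makes the
#' partition unambiguous for bouts straddling a boundary.
#'
#' @param inter an [detect_interactions()] result.
#' @param meal one-row meal data.frame.
#' @return data.frame of events ordered by time: `start_s`, `end_s` (end of
#'   the last sample, i.e. start + n_samples * dt), `n_samples`.
#' @export
extract_events <- function(inter, meal) {
  stopifnot(inherits(inter, "interaction_series"), nrow(meal) == 1L)
  runs <- .flag_runs(inter$flags)
  start_t <- inter$t0 + (runs$start - 1L) * inter$dt
  keep <- start_t >= meal$start_s - 1e-9 & start_t < meal$end_s - 1e-9
  data.frame(start_s = start_t[keep],
             end_s = start_t[keep] + runs$len[keep] * inter$dt,
             n_samples = runs$len[keep])
}

# maximal TRUE-runs of a logical vector: start index and length
.flag_runs <- function(f) {
  n <- length(f)
  if (n == 0L || !any(f)) return(data.frame(start = integer(), len = integer()))
  starts <- which(f & !c(FALSE, f[-n]))
  ends <- which(f & !c(f[-1L], FALSE))
  data.frame(start = starts, len = ends - starts + 1L)
}

#' Number of feeding events in a meal
#'
#' @param events data.frame from [extract_events()].
#' @return integer event count.
#' @export
events_per_meal <- function(events) {
  nrow(events)
}

#' Feeding rate: events per hour of meal
#'
#' @param n_events event count.
#' @param duration_h meal duration in hours (> 0).
#' @return events per hour.
#' @export
feeding_rate <- function(n_events, duration_h) {
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("degenerate meal: duration must be positive")
  n_events / duration_h
}

#' Feeding rate split at the meal peak
#'
#' Events are assigned to the pre-peak side when they start before the END
#' of the peak bin ("before and including the peak"); the peak bin's full
#' width counts as pre-peak time. Each event lands on exactly one side by
#' its start time, so the two counts always sum to the total.
#'
#' @param events data.frame from [extract_events()].
#' @param meal one-row meal data.frame carrying `start_bin`/`end_bin` so the
#'   bin width can be recovered, or pass `bin_width_s` explicitly.
#' @param bin_width_s width of the bins used to segment the meal, seconds.
#'   Defaults to the width implied by the meal's bin span.
#' @return one-row data.frame: `pre_events`, `post_events`,
#'   `pre_rate_per_h`, `post_rate_per_h` (NA when the corresponding
#'   duration is zero), `pre_time_h`, `post_time_h`.
#' @export
split_rate_at_peak <- function(events, meal, bin_width_s = NULL) {
  stopifnot(nrow(meal) == 1L)
  if (is.null(bin_width_s)) {
    n_bins <- meal$end_bin - meal$start_bin + 1L
    bin_width_s <- meal$duration_s / n_bins
  }
  boundary <- meal$peak_s + bin_width_s      # end of the peak bin
  pre_n <- sum(events$start_s < boundary - 1e-9)
  post_n <- nrow(events) - pre_n
  pre_h <- (boundary - meal$start_s) / 3600
  post_h <- (meal$end_s - boundary) / 3600
  data.frame(pre_events = pre_n, post_events = post_n,
             pre_rate_per_h = if (pre_h > 0) pre_n / pre_h else NA_real_,
             post_rate_per_h = if (post_h > 0) post_n / post_h else NA_real_,
             pre_time_h = pre_h, post_time_h = post_h)
}

#' Rate metrics bundle for one meal
#'
#' @param events data.frame from [extract_events()].
#' @param meal one-row meal data.frame.
#' @param bin_width_s see [split_rate_at_peak()].
#' @return one-row data.frame: `events_per_meal`, `rate_per_h`, plus the
#'   [split_rate_at_peak()] columns.
#' @export
rate_metrics <- function(events, meal, bin_width_s = NULL) {
  n <- events_per_meal(events)
  duration_h <- (meal$end_s - meal$start_s) / 3600
  cbind(data.frame(events_per_meal = n,
                   rate_per_h = feeding_rate(n, duration_h)),
        split_rate_at_peak(events, meal, bin_width_s))
}
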