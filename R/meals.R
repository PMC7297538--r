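#' Split a binned record into 24 h day windows
#'
#' Days are contiguous, non-overlapping 24 h windows anchored at the
#' experiment start plus an optional offset. Days are numbered from 1. The
#' recordings are run in constant darkness, so the day boundary is a
#' configuration choice, not a lights-on time.
#'
#' @param binned a [bin_interactions()] result.
#' @param t0_offset_s offset of the first day boundary from the series' t0,
#'   seconds. Default 0.
#' @return data.frame with columns `day` (1-based), `start_s`, `end_s`,
#'   `partial` (TRUE when the recording does not cover the full window).
#' @export
split_days <- function(binned, t0_offset_s = 0) {
  stopifnot(inherits(binned, "binned_counts"))
  if (length(binned$counts) < 1L) stop("empty binned record")
  span_end <- binned$bin_start_times[length(binned$counts)] + binned$bin_width_s
  start0 <- binned$t0 + t0_offset_s
  n_days <- max(1L, as.integer(ceiling((span_end - start0) / 86400 - 1e-9)))
  starts <- start0 + (seq_len(n_days) - 1L) * 86400
  data.frame(day = seq_len(n_days),
             start_s = starts,
             end_s = starts + 86400,
             partial = starts + 86400 > span_end + 1e-9)
}

.day_bin_idx <- function(binned, day) {
  which(binned$bin_start_times >= day$start_s - 1e-9 &
          binned$bin_start_times < day$end_s - 1e-9)
}

#' Segment one day's binned counts into meals
#'
#' A meal is a maximal run of bins whose count reaches the day-relative
#' threshold `max(1, ceiling(min_frac * max(day counts)))`, allowing up to
#' `gap_bins` consecutive sub-threshold bins inside the run. The meal peak
#' is the earliest bin with the maximal count within the run.
#'
#' @param binned a [bin_interactions()] result.
#' @param day one row of [split_days()] (data.frame or list with `day`,
#'   `start_s`, `end_s`).
#' @param min_frac fraction of the day's maximum bin count a bin must reach
#'   to seed/extend a meal, 0 < min_frac < 1. Default 0.1.
#' @param gap_bins number of consecutive sub-threshold bins tolerated
#'   inside a meal (>= 0). Default 1.
#' @return data.frame of meals ordered by start time, with columns `day`,
#'   `start_bin`, `end_bin`, `peak_bin` (global 1-based bin indices),
#'   `start_s`, `end_s`, `peak_s`, `size`, `duration_s`. Zero rows when the
#'   day has no above-threshold bin.
#' @export
segment_meals <- function(binned, day, min_frac = 0.1, gap_bins = 1) {
  stopifnot(inherits(binned, "binned_counts"))
  if (!(min_frac > 0 && min_frac < 1)) stop("min_frac must be in (0, 1)")
  if (gap_bins < 0) stop("gap_bins must be >= 0")
  idx <- .day_bin_idx(binned, day)
  counts <- binned$counts[idx]
  empty <- data.frame(day = integer(), start_bin = integer(),
                      end_bin = integer(), peak_bin = integer(),
                      start_s = numeric(), end_s = numeric(),
                      peak_s = numeric(), size = integer(),
                      duration_s = numeric())
  if (length(counts) == 0L || max(counts) == 0L) return(empty)
  thr <- max(1L, as.integer(ceiling(min_frac * max(counts))))
  above <- counts >= thr
  if (!any(above)) return(empty)
  # close gaps of up to gap_bins sub-threshold bins between above-runs
  runs <- rle(above)
  if (gap_bins > 0L && length(runs$lengths) > 2L) {
    for (k in seq_along(runs$lengths)) {
      if (!runs$values[k] && k > 1L && k < length(runs$lengths) &&
          runs$lengths[k] <= gap_bins) {
        runs$values[k] <- TRUE
      }
    }
    above <- inverse.rle(runs)
    runs <- rle(above)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  meal_rows <- lapply(which(runs$values), function(k) {
    rel <- starts[k]:ends[k]
    g <- idx[rel]                       # global bin indices
    cc <- binned$counts[g]
    peak_rel <- which.max(cc)           # earliest maximal bin
    data.frame(day = as.integer(day$day),
               start_bin = g[1L], end_bin = g[length(g)],
               peak_bin = g[peak_rel],
               start_s = binned$bin_start_times[g[1L]],
               end_s = binned$bin_start_times[g[length(g)]] +
                 binned$bin_width_s,
               peak_s = binned$bin_start_times[g[peak_rel]],
               size = as.integer(sum(cc)),
               duration_s = length(g) * binned$bin_width_s)
  })
  out <- do.call(rbind, meal_rows)
  out[out$size >= 1L, , drop = FALSE]
}

#' Select the evening meal of a day
#'
#' The evening meal is used for all meal-based calculations to control for
#' variability in meal shape. A meal qualifies when its peak falls inside
#' the configured subjective-evening window (hours after the day start);
#' among qualifiers the largest (by interaction count) wins, ties going to
#' the earliest. When no meal qualifies the day's largest meal is returned
#' with `fallback = TRUE`.
#'
#' @param meals data.frame from [segment_meals()] (one day's meals).
#' @param day the corresponding [split_days()] row.
#' @param evening_h length-2 numeric, start/end of the subjective-evening
#'   window in hours after the day start. Default c(9, 15).
#' @return one-row data.frame (the meal plus a `fallback` column), or
#'   `NULL` when the day has no meals.
#' @export
select_evening_meal <- function(meals, day, evening_h = c(9, 15)) {
  if (is.null(meals) || nrow(meals) == 0L) return(NULL)
  peak_h <- (meals$peak_s - day$start_s) / 3600
  in_win <- peak_h >= evening_h[1L] & peak_h < evening_h[2L]
  pool <- if (any(in_win)) meals[in_win, , drop = FALSE] else meals
  pick <- pool[order(-pool$size, pool$start_s), , drop = FALSE][1L, ,
                                                               drop = FALSE]
  pick$fallback <- !any(in_win)
  rownames(pick) <- NULL
  pick
}

#' Meal microstructure metrics
#'
#' Meal size is the interaction count between meal start and end; duration,
#' pre-peak duration (peak - start, a proxy for appetitive build-up) and
#' post-peak duration (end - peak, the satiation proxy) are reported in
#' hours. `duration_h = pre_peak_h + post_peak_h` exactly, with the peak
#' placed at the start of the peak bin.
#'
#' @param meal one-row meal data.frame (from [segment_meals()] or
#'   [select_evening_meal()]).
#' @return one-row data.frame: `size`, `duration_h`, `pre_peak_h`,
#'   `post_peak_h`.
#' @export
meal_metrics <- function(meal) {
  stopifnot(nrow(meal) == 1L)
  pre <- (meal$peak_s - meal$start_s) / 3600
  post <- (meal$end_s - meal$peak_s) / 3600
  data.frame(size = meal$size,
             duration_h = (meal$end_s - meal$start_s) / 3600,
             pre_peak_h = pre, post_peak_h = post)
}

#' Total food interactions in one day
#'
#' @param binned a [bin_interactions()] result.
#' @param day one [split_days()] row.
#' @return integer count of interactions in the day's bins.
#' @export
daily_interactions <- function(binned, day) {
  as.integer(sum(binned$counts[.day_bin_idx(binned, day)]))
}
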