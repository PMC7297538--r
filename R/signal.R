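#' Moving-median baseline of a raw trace
#'
#' Estimates the slowly varying capacitance baseline as a centered rolling
#' median, truncated at the trace edges. The median resists the brief
#' positive excursions produced by food interactions, which a rolling mean
#' would absorb into the baseline.
#'
#' The centered window around sample `i` contains all samples `j` with
#' `|j - i| * dt <= window_s / 2`; interior windows therefore hold
#' `2 * floor(window_s / (2 dt)) + 1` samples, and windows near the edges
#' shrink.
#'
#' @param trace a [flic_trace()].
#' @param window_s window length in seconds (>= 3 * dt). Default 120 s.
#' @return object of class `baseline_series`: fields `values` (same length
#'   and clock as the trace), `window_s`, `t0`, `dt`.
#' @export
moving_baseline <- function(trace, window_s = 120) {
  stopifnot(inherits(trace, "flic_trace"))
  n <- length(trace$values)
  if (n < 1L) stop("empty trace")
  if (window_s < 3 * trace$dt - 1e-9)
    stop("window_s must be at least 3 samples wide")
  h <- max(1L, as.integer(floor(window_s / (2 * trace$dt))))
  k <- 2L * h + 1L
  x <- trace$values
  if (n >= k) {
    base <- as.vector(stats::runmed(x, k, endrule = "keep"))
    # truncated windows at the edges: brute-force medians
    edge <- seq_len(h)
    base[edge] <- vapply(edge, function(i)
      stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
    edge_r <- (n - h + 1L):n
    base[edge_r] <- vapply(edge_r, function(i)
      stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
  } else {
    base <- vapply(seq_len(n), function(i)
      stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
  }
  structure(
    list(values = base, window_s = window_s, t0 = trace$t0, dt = trace$dt),
    class = "baseline_series"
  )
}

#' Detect food-interaction samples
#'
#' Flags sample `i` as a food interaction when the signal exceeds the
#' baseline by strictly more than `threshold` AU:
#' `values[i] - baseline[i] > threshold`. The strict inequality follows the
#' closed-loop trigger rule ("signal over 10"); the default threshold is
#' 10 AU.
#'
#' @param trace a [flic_trace()].
#' @param baseline a [moving_baseline()] result on the same clock.
#' @param threshold AU above baseline required (> 0). Default 10.
#' @return object of class `interaction_series`: logical `flags` plus
#'   `threshold`, `t0`, `dt`.
#' @export
detect_interactions <- function(trace, baseline, threshold = 10) {
  stopifnot(inherits(trace, "flic_trace"))
  if (length(baseline$values) != length(trace$values))
    stop("trace and baseline lengths differ")
  if (!isTRUE(all.equal(baseline$t0, trace$t0)) ||
      !isTRUE(all.equal(baseline$dt, trace$dt)))
    stop("trace and baseline must share the same clock")
  if (threshold <= 0) stop("threshold must be positive")
  structure(
    list(flags = (trace$values - baseline$values) > threshold,
         threshold = threshold, t0 = trace$t0, dt = trace$dt),
    class = "interaction_series"
  )
}

#' Sum interaction flags into fixed-width time bins
#'
#' Bins are contiguous half-open intervals `[start, start + width)`
#' anchored at the series' `t0`. The default width is 1800 s (30 min). A
#' trailing bin not fully covered by samples is kept and flagged partial.
#'
#' @param inter an [detect_interactions()] result.
#' @param bin_width_s bin width in seconds; must be a positive multiple of
#'   the sample period (tolerance 1e-9 s). Default 1800.
#' @return object of class `binned_counts`: integer `counts`,
#'   `bin_start_times` (seconds), `bin_width_s`, `partial_last` flag,
#'   `t0`, `dt`.
#' @export
bin_interactions <- function(inter, bin_width_s = 1800) {
  stopifnot(inherits(inter, "interaction_series"))
  ratio <- bin_width_s / inter$dt
  if (bin_width_s <= 0 || abs(ratio - round(ratio)) > 1e-9 / inter$dt)
    stop("bin_width_s must be a positive multiple of dt")
  per_bin <- as.integer(round(ratio))
  n <- length(inter$flags)
  n_bins <- as.integer(ceiling(n / per_bin))
  bin_idx <- ((seq_len(n) - 1L) %/% per_bin) + 1L
  counts <- as.integer(tabulate(bin_idx[inter$flags], nbins = n_bins))
  structure(
    list(counts = counts,
         bin_start_times = inter$t0 + (seq_len(n_bins) - 1L) * bin_width_s,
         bin_width_s = bin_width_s,
         partial_last = (n %% per_bin) != 0L,
         t0 = inter$t0, dt = inter$dt),
    class = "binned_counts"
  )
}

#' Tidy data frame of binned counts
#'
#' @param binned a [bin_interactions()] result.
#' @param channel_id optional channel label column.
#' @return data.frame with columns `channel`, `bin_start_s`, `count`.
#' @export
binned_counts_df <- function(binned, channel_id = "ch1") {
  data.frame(channel = channel_id,
             bin_start_s = binned$bin_start_times,
             count = binned$counts,
             stringsAsFactors = FALSE)
}
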