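#' Construct a stimulus-locked fluorescence trace
#'
#' One region of interest's raw fluorescence per frame, with the frame index
#' of stimulus delivery. The imaging frame period defaults to 0.254 s.
#' The same container and metrics serve GCaMP calcium traces and
#' pHluorin vesicular-release traces.
#'
#' @param values raw fluorescence per frame (AU), finite.
#' @param stim_frame 1-based frame index of stimulus delivery.
#' @param frame_period_s frame period, seconds. Default 0.254.
#' @param roi_id ROI identifier (two ROIs per fly in the sucrose/water
#'   stimulation experiments).
#' @return object of class `calcium_trace`.
#' @export
calcium_trace <- function(values, stim_frame, frame_period_s = 0.254,
                          roi_id = "roi1") {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("fluorescence values must be finite")
  if (stim_frame < 1L || stim_frame > length(values))
    stop("stim_frame outside the trace")
  structure(list(roi_id = roi_id, frame_period_s = frame_period_s,
                 values = values, stim_frame = as.integer(stim_frame)),
            class = "calcium_trace")
}

#' Compute the dF/F0 trace
#'
#' F0 is the mean of the `baseline_frames` frames recorded immediately
#' prior to the stimulus; dF/F0 = (F - F0) / F0, a dimensionless fraction
#' (multiply by 100 for the % scale used in figures).
#'
#' @param trace a [calcium_trace()].
#' @param baseline_frames number of pre-stimulus frames averaged for F0.
#'   Default 10.
#' @return object of class `dff_trace`: `values` (per-frame dF/F0), `f0`,
#'   `stim_frame`, `frame_period_s`, `baseline_frames`.
#' @export
compute_dff <- function(trace, baseline_frames = 10) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (trace$stim_frame <= baseline_frames)
    stop("stim_frame must leave room for ", baseline_frames,
         " baseline frames")
  idx <- (trace$stim_frame - baseline_frames):(trace$stim_frame - 1L)
  f0 <- mean(trace$values[idx])
  if (f0 <= 0) stop("baseline fluorescence must be positive")
  structure(list(values = (trace$values - f0) / f0, f0 = f0,
                 stim_frame = trace$stim_frame,
                 frame_period_s = trace$frame_period_s,
                 baseline_frames = baseline_frames,
                 roi_id = trace$roi_id),
            class = "dff_trace")
}

#' Detect the response window of a dF/F0 trace
#'
#' The response initiates at the first frame at or after the stimulus whose
#' dF/F0 exceeds `k_sigma` times the baseline-frame standard deviation, and
#' ends at the last frame before the trace falls back to or below that
#' level after the in-window peak (or at the last frame if it never does).
#'
#' @param dff a [compute_dff()] result.
#' @param k_sigma threshold multiplier on the baseline SD. Default 2.
#' @return list `(start_frame, end_frame, threshold)` or `NULL` when no
#'   frame crosses the threshold.
#' @export
detect_response_window <- function(dff, k_sigma = 2) {
  stopifnot(inherits(dff, "dff_trace"))
  if (dff$baseline_frames < 2L)
    stop("need >= 2 baseline frames to estimate noise")
  bidx <- (dff$stim_frame - dff$baseline_frames):(dff$stim_frame - 1L)
  thr <- k_sigma * stats::sd(dff$values[bidx])
  n <- length(dff$values)
  post <- dff$stim_frame:n
  cross <- post[dff$values[post] > thr]
  if (length(cross) == 0L) return(NULL)
  start <- cross[1L]
  peak <- start - 1L + which.max(dff$values[start:n])
  after <- if (peak < n) (peak + 1L):n else integer(0)
  fall <- after[dff$values[after] <= thr]
  end <- if (length(fall) > 0L) fall[1L] - 1L else n
  list(start_frame = start, end_frame = end, threshold = thr)
}

#' Transient metrics: peak, latency-to-peak, AUC
#'
#' Peak dF/F0 is the single maximum acquired within the response window
#' (ties broken by the earliest frame); latency is the time from stimulus
#' delivery to the peak; AUC is the sum of the dF/F0 values from the
#' initiation of the response to its end (set `time_weighted = TRUE` to
#' multiply by the frame period for a seconds-weighted area).
#'
#' @param dff a [compute_dff()] result.
#' @param window a [detect_response_window()] result; `NULL` yields
#'   zero-metrics with `responded = FALSE`.
#' @param time_weighted multiply the AUC by the frame period? Default FALSE.
#' @return one-row data.frame: `peak_dff`, `latency_s`, `auc`,
#'   `window_start`, `window_end`, `responded`.
#' @export
trace_metrics <- function(dff, window = detect_response_window(dff),
                          time_weighted = FALSE) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.null(window)) {
    return(data.frame(peak_dff = 0, latency_s = NA_real_, auc = 0,
                      window_start = NA_integer_, window_end = NA_integer_,
                      responded = FALSE))
  }
  idx <- window$start_frame:window$end_frame
  vals <- dff$values[idx]
  peak_rel <- which.max(vals)
  peak_frame <- idx[peak_rel]
  auc <- sum(vals)
  if (time_weighted) auc <- auc * dff$frame_period_s
  data.frame(peak_dff = vals[peak_rel],
             latency_s = (peak_frame - dff$stim_frame) * dff$frame_period_s,
             auc = auc,
             window_start = window$start_frame,
             window_end = window$end_frame,
             responded = TRUE)
}

#' Read a fluorescence trace table
#'
#' Long layout: one row per frame with columns for the ROI id, the raw
#' fluorescence, and a stimulus flag column that is nonzero on the
#' stimulus-delivery frame.
#'
#' @param path delimited text file.
#' @param layout list: `roi_col`, `f_col`, `stim_col` (names or indices;
#'   defaults "roi", "F", "stim"), `frame_period_s` (default 0.254).
#' @param sep field separator. Default ",".
#' @return list of [calcium_trace()] objects, one per ROI.
#' @export
read_trace_table <- function(path, layout = list(), sep = ",") {
  roi_col <- if (!is.null(layout$roi_col)) layout$roi_col else "roi"
  f_col <- if (!is.null(layout$f_col)) layout$f_col else "F"
  stim_col <- if (!is.null(layout$stim_col)) layout$stim_col else "stim"
  period <- if (!is.null(layout$frame_period_s)) layout$frame_period_s
            else 0.254
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) < 1L) stop("empty trace table: ", path)
  rois <- df[[.col_index(df, roi_col)]]
  fvals <- .numeric_column(df, f_col, path)
  stim <- .numeric_column(df, stim_col, path)
  lapply(unique(rois), function(r) {
    sel <- rois == r
    sf <- which(stim[sel] != 0)
    if (length(sf) == 0L)
      stop("no stimulus marker for ROI ", r, " in ", path)
    calcium_trace(fvals[sel], stim_frame = sf[1L],
                  frame_period_s = period, roi_id = as.character(r))
  })
}

#' Per-ROI metrics table for a set of traces
#'
#' @param traces list of [calcium_trace()] objects.
#' @param baseline_frames see [compute_dff()]. Default 10.
#' @param k_sigma see [detect_response_window()]. Default 2.
#' @param time_weighted see [trace_metrics()]. Default FALSE.
#' @return data.frame with one row per ROI: `roi`, plus the
#'   [trace_metrics()] columns.
#' @export
ca_metrics_table <- function(traces, baseline_frames = 10, k_sigma = 2,
                             time_weighted = FALSE) {
  rows <- lapply(traces, function(tr) {
    dff <- compute_dff(tr, baseline_frames)
    m <- trace_metrics(dff, detect_response_window(dff, k_sigma),
                       time_weighted)
    cbind(data.frame(roi = tr$roi_id, stringsAsFactors = FALSE), m)
  })
  do.call(rbind, rows)
}
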