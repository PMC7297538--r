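#' Construct a raw FLIC signal trace
#'
#' A `flic_trace` holds one channel of a capacitive feeding monitor: a
#' uniformly sampled signal in arbitrary capacitance units (AU). The FLIC
#' samples every 200 ms, so `dt` defaults to 0.2 s; the timestamp of sample
#' `i` (1-based) is `t0 + (i - 1) * dt` on the experiment clock.
#'
#' @param values numeric vector of signal samples (AU); finite, length >= 1.
#' @param dt sample period in seconds (> 0).
#' @param t0 experiment-clock time of the first sample, seconds.
#' @param channel_id channel identifier (typically one well = one fly).
#' @return an object of class `flic_trace` with fields `channel_id`, `t0`,
#'   `dt`, `values`.
#' @export
flic_trace <- function(values, dt = 0.2, t0 = 0, channel_id = "ch1") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar")
  structure(
    list(channel_id = channel_id, t0 = as.numeric(t0), dt = as.numeric(dt),
         values = values),
    class = "flic_trace"
  )
}

#' @export
print.flic_trace <- function(x, ...) {
  cat(sprintf("<flic_trace %s: %d samples @ %.3g s, t0 = %.1f s (%.2f h)>\n",
              x$channel_id, length(x$values), x$dt, x$t0,
              length(x$values) * x$dt / 3600))
  invisible(x)
}

#' Sample timestamps of a trace-like object
#'
#' @param x object with `t0`, `dt` and `values` (or `flags`) fields.
#' @return numeric vector of experiment-clock times, seconds.
#' @export
sample_times <- function(x) {
  n <- length(if (!is.null(x$values)) x$values else x$flags)
  x$t0 + (seq_len(n) - 1L) * x$dt
}

#' Read FLIC-monitor-style delimited text into raw traces
#'
#' Parses a delimited file with one row per sample and one column per
#' channel, optionally with a time column. Missing values (empty cells or
#' NA) are forward-filled and counted; runs of missing samples longer than
#' `max_gap_s` split the channel into separate trace segments (each with its
#' own `t0`).
#'
#' @param path file path to delimited text.
#' @param layout list describing the columns: `time_col` (name or index of
#'   the time column, or `NULL` for implied uniform sampling), `signal_cols`
#'   (names or indices of signal columns; default all non-time columns),
#'   `dt` (sample period when no time column; default 0.2), `t0` (clock
#'   start when no time column; default 0).
#' @param sep field separator, default ",".
#' @param header does the file have a header row? Default `TRUE`.
#' @param max_gap_s gaps of missing data longer than this split the trace
#'   (default 10 s).
#' @return list of `flic_trace` objects, one per channel segment. Each
#'   carries attributes `n_filled` (forward-filled samples) and `segment`.
#' @export
read_flic_csv <- function(path, layout = list(), sep = ",", header = TRUE,
                          max_gap_s = 10) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, blank.lines.skip = FALSE)
  if (nrow(df) < 1L) stop("empty input file: ", path)
  time_col <- layout$time_col
  if (!is.null(time_col)) {
    tvals <- .numeric_column(df, time_col, path)
    if (any(diff(tvals) <= 0))
      stop("time column must be strictly increasing in ", path)
    dt <- stats::median(diff(tvals))
    t0 <- tvals[1L]
    sig_cols <- layout$signal_cols
    if (is.null(sig_cols)) {
      sig_cols <- setdiff(seq_len(ncol(df)), .col_index(df, time_col))
    }
  } else {
    dt <- if (!is.null(layout$dt)) layout$dt else 0.2
    t0 <- if (!is.null(layout$t0)) layout$t0 else 0
    tvals <- t0 + (seq_len(nrow(df)) - 1L) * dt
    sig_cols <- layout$signal_cols
    if (is.null(sig_cols)) sig_cols <- seq_len(ncol(df))
  }
  traces <- list()
  for (sc in sig_cols) {
    vals <- .numeric_column(df, sc, path)
    nm <- if (is.character(sc)) sc else colnames(df)[sc]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- paste0("ch", sc)
    traces <- c(traces, .fill_and_split(vals, tvals, dt, nm, max_gap_s))
  }
  traces
}

.col_index <- function(df, col) {
  if (is.character(col)) match(col, colnames(df)) else as.integer(col)
}

.numeric_column <- function(df, col, path) {
  idx <- .col_index(df, col)
  if (is.na(idx) || idx < 1L || idx > ncol(df))
    stop("column not found: ", col)
  raw <- df[[idx]]
  suppress_empty <- is.character(raw) & !is.na(raw) & trimws(raw) == ""
  raw[suppress_empty] <- NA
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(vals))
  if (length(bad) > 0L)
    stop(sprintf("non-numeric value in %s at row %d, column %s",
                 path, bad[1L], as.character(col)))
  vals
}

# Forward-fill NAs; gaps longer than max_gap_s split into segments.
.fill_and_split <- function(vals, tvals, dt, channel_id, max_gap_s) {
  n <- length(vals)
  miss <- is.na(vals)
  if (all(miss)) stop("channel ", channel_id, " contains no data")
  gap_run <- rle(miss)
  # segment boundaries: long NA runs
  seg_break <- rep(FALSE, n)
  pos <- cumsum(c(1L, gap_run$lengths))
  for (k in seq_along(gap_run$lengths)) {
    if (gap_run$values[k] && gap_run$lengths[k] * dt > max_gap_s) {
      seg_break[pos[k]:(pos[k + 1L] - 1L)] <- TRUE
    }
  }
  keep_runs <- rle(!seg_break)
  starts <- cumsum(c(1L, keep_runs$lengths))
  out <- list()
  seg_i <- 0L
  for (k in seq_along(keep_runs$lengths)) {
    if (!keep_runs$values[k]) next
    idx <- starts[k]:(starts[k + 1L] - 1L)
    v <- vals[idx]
    # leading NAs in a segment: backfill from first observed value
    first_obs <- which(!is.na(v))[1L]
    if (is.na(first_obs)) next
    if (first_obs > 1L) v[seq_len(first_obs - 1L)] <- v[first_obs]
    n_filled <- sum(is.na(v))
    v <- .locf(v)
    seg_i <- seg_i + 1L
    tr <- flic_trace(v, dt = dt, t0 = tvals[idx[1L]],
                     channel_id = channel_id)
    attr(tr, "n_filled") <- n_filled
    attr(tr, "segment") <- seg_i
    out[[length(out) + 1L]] <- tr
  }
  out
}

.locf <- function(v) {
  idx <- cumsum(!is.na(v))
  obs <- v[!is.na(v)]
  obs[pmax(idx, 1L)]
}
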