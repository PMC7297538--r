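# Independent brute-force oracles used across the suite. These deliberately
# recompute everything per index / per case, by definitions only.

# centered rolling median with edge truncation, per-index
oracle_baseline <- function(values, dt, window_s) {
  h <- max(1, floor(window_s / (2 * dt)))
  n <- length(values)
  vapply(seq_len(n), function(i) {
    stats::median(values[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# maximal TRUE-runs via which() + gap splitting (no rle)
oracle_runs <- function(flags) {
  idx <- which(flags)
  if (length(idx) == 0L)
    return(data.frame(start = integer(), len = integer()))
  grp <- cumsum(c(1L, as.integer(diff(idx) > 1L)))
  starts <- as.integer(tapply(idx, grp, min))
  lens <- as.integer(tapply(idx, grp, length))
  data.frame(start = starts, len = lens)
}

# meal runs on one day's counts: explicit scan with gap tolerance
oracle_meal_runs <- function(counts, thr, gap_bins) {
  above <- counts >= thr
  runs <- list()
  i <- 1L
  n <- length(counts)
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    start <- i
    end <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (above[j]) { end <- j; gap <- 0L }
      else { gap <- gap + 1L; if (gap > gap_bins) break }
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(start, end)
    i <- j + 1L
  }
  runs
}

# two-sided Mann-Whitney p by full enumeration of label assignments
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  mu <- n1 * (n - n1) / 2
  u_of <- function(sel) {
    r <- rank(pool)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  obs <- abs(u_of(seq_len(n1)) - mu)
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(sel) abs(u_of(sel) - mu))
  mean(stats >= obs - 1e-9)
}

# quick constant-drift trace with spikes at known samples
spike_trace <- function(n, spikes = integer(), level = 100, excess = 50,
                        dt = 0.2) {
  v <- rep(level, n)
  v[spikes] <- level + excess
  flic_trace(v, dt = dt)
}
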