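mk_inter <- function(flags, dt = 0.2, t0 = 0) {
  structure(list(flags = flags, threshold = 10, t0 = t0, dt = dt),
            class = "interaction_series")
}

mk_meal <- function(start_s, end_s, peak_s, n_bins = NULL, width = 1800) {
  if (is.null(n_bins)) n_bins <- round((end_s - start_s) / width)
  data.frame(day = 1L, start_bin = 1L, end_bin = n_bins,
             peak_bin = 1L + round((peak_s - start_s) / width),
             start_s = start_s, end_s = end_s, peak_s = peak_s,
             size = 1L, duration_s = end_s - start_s)
}

test_that("extract_events splits bouts exactly at single false samples", {
  meal <- mk_meal(0, 1800, 0)
  ev <- extract_events(mk_inter(c(FALSE, TRUE, TRUE, FALSE, TRUE)), meal)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_samples, c(2L, 1L))
  expect_equal(ev$start_s, c(0.2, 0.8))

  # all-true / all-false meals
  expect_equal(nrow(extract_events(mk_inter(rep(TRUE, 50)), meal)), 1L)
  expect_equal(nrow(extract_events(mk_inter(rep(FALSE, 50)), meal)), 0L)
})

test_that("event extraction equals naive run splitting on random vectors", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(10:5000, 1)
    flags <- runif(n) < runif(1, 0.05, 0.6)
    meal <- mk_meal(0, n * 0.2 + 1800, 0)
    ev <- extract_events(mk_inter(flags), meal)
    oracle <- oracle_runs(flags)
    expect_equal(nrow(ev), nrow(oracle))
    expect_equal(ev$n_samples, oracle$len)
    expect_equal(ev$start_s, (oracle$start - 1) * 0.2)
  }
})

test_that("events partition the meal's interaction samples", {
  set.seed(52)
  flags <- runif(20000) < 0.3
  meal <- mk_meal(0, 20000 * 0.2 + 1800, 1800)
  ev <- extract_events(mk_inter(flags), meal)
  # every true flag in exactly one event, count bounded by flags
  expect_equal(sum(ev$n_samples), sum(flags))
  expect_lte(events_per_meal(ev), sum(flags))
  # maximality: no event ends exactly one sample before the next begins
  gaps <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
  expect_true(all(gaps > 0.2 - 1e-9))
  # transition-count oracle
  n_trans <- sum(diff(c(FALSE, flags)) == 1L)
  expect_equal(events_per_meal(ev), n_trans)
})

test_that("events outside the meal window are excluded by start time", {
  flags <- rep(FALSE, 36000)      # 2 h at 5 Hz
  flags[c(100:105, 9002:9010, 20000:20005)] <- TRUE
  # meal = first 30-min bin only
  meal <- mk_meal(0, 1800, 0, n_bins = 1)
  ev <- extract_events(mk_inter(flags), meal)
  expect_equal(nrow(ev), 1L)      # only the bout starting at sample 100
  # bout starting exactly at end_s belongs to the next bin
  flags2 <- rep(FALSE, 36000)
  flags2[9001] <- TRUE            # starts at t = 1800 s exactly
  expect_equal(nrow(extract_events(mk_inter(flags2), meal)), 0L)
})

test_that("feeding_rate is events over duration with guarded degenerates", {
  expect_equal(feeding_rate(12, 4), 3)
  expect_equal(feeding_rate(0, 2), 0)
  expect_error(feeding_rate(3, 0), "degenerate")
  # identity: rate x duration returns the count
  set.seed(53)
  for (i in 1:10) {
    n <- rpois(1, 20); d <- runif(1, 0.5, 8)
    expect_equal(feeding_rate(n, d) * d, n)
  }
})

test_that("split_rate_at_peak assigns by start time at the peak-bin end", {
  # meal 0-6 h, peak bin 2-2.5 h (bin 5 of the meal): pre time 2.5 h
  meal <- mk_meal(0, 6 * 3600, 2 * 3600)
  ev <- data.frame(start_s = c(1000, 5000, 8000, 8999, 9000, 12000, 20000),
                   end_s = NA, n_samples = 1L)
  sp <- split_rate_at_peak(ev, meal)
  expect_equal(sp$pre_events, 4L)      # start < 9000 s
  expect_equal(sp$post_events, 3L)
  expect_equal(sp$pre_time_h, 2.5)
  expect_equal(sp$post_time_h, 3.5)
  expect_equal(sp$pre_rate_per_h, 4 / 2.5)
  expect_equal(sp$post_rate_per_h, 3 / 3.5)
  expect_equal(sp$pre_events + sp$post_events, nrow(ev))

  # all events pre-peak -> post rate 0
  ev2 <- data.frame(start_s = c(100, 200), end_s = NA, n_samples = 1L)
  expect_equal(split_rate_at_peak(ev2, meal)$post_rate_per_h, 0)

  # peak in the last bin -> post duration 0 -> post rate missing
  meal_end <- mk_meal(0, 6 * 3600, 5.5 * 3600)
  expect_true(is.na(split_rate_at_peak(ev2, meal_end)$post_rate_per_h))
})

test_that("rate_metrics bundles counts and rates coherently", {
  meal <- mk_meal(0, 4 * 3600, 3600)
  ev <- data.frame(start_s = seq(0, 14000, length.out = 12), end_s = NA,
                   n_samples = 2L)
  rm_ <- rate_metrics(ev, meal)
  expect_equal(rm_$events_per_meal, 12L)
  expect_equal(rm_$rate_per_h, 3)
  expect_equal(rm_$pre_events + rm_$post_events, 12L)
})
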