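# small binned_counts builder: one count per 30-min bin
mk_bins <- function(counts, width = 1800, t0 = 0) {
  structure(list(counts = as.integer(counts),
                 bin_start_times = t0 + (seq_along(counts) - 1) * width,
                 bin_width_s = width, partial_last = FALSE,
                 t0 = t0, dt = 0.2),
            class = "binned_counts")
}

test_that("split_days cuts contiguous 24 h windows with offset", {
  b <- mk_bins(rep(1, 96))                      # 48 h
  d <- split_days(b)
  expect_equal(nrow(d), 2L)
  expect_false(any(d$partial))
  expect_equal(d$start_s, c(0, 86400))

  d <- split_days(mk_bins(rep(1, 72)))          # 36 h
  expect_equal(d$partial, c(FALSE, TRUE))

  d6 <- split_days(mk_bins(rep(1, 96)), t0_offset_s = 6 * 3600)
  expect_equal(d6$start_s, c(0, 86400) + 6 * 3600)
})

test_that("segment_meals matches brute-force run enumeration", {
  counts <- c(0, 0, 5, 9, 4, 0, 0, rep(0, 41))
  b <- mk_bins(counts)
  day <- split_days(b)[1, ]
  meals <- segment_meals(b, day, min_frac = 0.2, gap_bins = 0)
  expect_equal(nrow(meals), 1L)
  expect_equal(meals$start_bin, 3L)
  expect_equal(meals$end_bin, 5L)
  expect_equal(meals$peak_bin, 4L)
  expect_equal(meals$size, 18L)

  # all-zero day: no meals, not an error
  expect_equal(nrow(segment_meals(mk_bins(rep(0, 48)), day)), 0L)

  # gap closure: two runs separated by one zero bin
  counts <- c(rep(0, 4), 6, 7, 0, 5, 6, rep(0, 39))
  b <- mk_bins(counts)
  expect_equal(nrow(segment_meals(b, day, 0.2, gap_bins = 1)), 1L)
  expect_equal(nrow(segment_meals(b, day, 0.2, gap_bins = 0)), 2L)

  # random days vs the scan oracle
  set.seed(31)
  for (rep_i in 1:25) {
    counts <- rpois(48, 1.2) * rbinom(48, 1, 0.4)
    b <- mk_bins(counts)
    for (gap in 0:2) {
      meals <- segment_meals(b, day, 0.15, gap)
      thr <- max(1, ceiling(0.15 * max(counts)))
      oracle <- oracle_meal_runs(counts, thr, gap)
      if (max(counts) == 0) {
        expect_equal(nrow(meals), 0L)
        next
      }
      expect_equal(nrow(meals), length(oracle))
      for (k in seq_along(oracle)) {
        expect_equal(meals$start_bin[k], oracle[[k]][1])
        expect_equal(meals$end_bin[k], oracle[[k]][2])
      }
    }
  }
})

test_that("peak ties break to the earliest maximal bin", {
  b <- mk_bins(c(0, 4, 7, 2, 7, 4, rep(0, 42)))
  meals <- segment_meals(b, split_days(b)[1, ], 0.2, 0)
  expect_equal(meals$peak_bin, 3L)
})

test_that("segmentation ignores all-zero bins outside the day", {
  counts <- c(rep(0, 10), 3, 8, 5, rep(0, 35))
  b1 <- mk_bins(counts)
  b2 <- mk_bins(c(counts, rep(0, 48)))          # extra empty day appended
  day <- split_days(b1)[1, ]
  expect_equal(segment_meals(b1, day, 0.2, 1), segment_meals(b2, day, 0.2, 1))
})

test_that("select_evening_meal prefers in-window meals, largest, earliest", {
  day <- data.frame(day = 1L, start_s = 0, end_s = 86400)
  counts <- rep(0, 48)
  counts[21:23] <- c(5, 9, 5)                   # peak hour 10.5 (in window)
  b <- mk_bins(counts)
  meals <- segment_meals(b, day, 0.1, 0)
  pick <- select_evening_meal(meals, day)
  expect_equal(pick$peak_bin, 22L)
  expect_false(pick$fallback)

  # two in-window meals: sizes 40 vs 90 -> the larger
  counts <- rep(0, 48)
  counts[20:21] <- c(20, 20)
  counts[26:28] <- c(30, 40, 20)
  b <- mk_bins(counts)
  meals <- segment_meals(b, day, 0.05, 0)
  expect_equal(nrow(meals), 2L)
  pick <- select_evening_meal(meals, day)
  expect_equal(pick$size, 90L)

  # only a morning meal -> fallback flagged
  counts <- rep(0, 48)
  counts[5:6] <- c(10, 12)                      # peak hour 2.5
  b <- mk_bins(counts)
  pick <- select_evening_meal(segment_meals(b, day, 0.1, 0), day)
  expect_true(pick$fallback)
  expect_equal(pick$size, 22L)

  # empty meal list -> NULL
  expect_null(select_evening_meal(segment_meals(mk_bins(rep(0, 48)), day),
                                  day))
})

test_that("meal metrics are exact subtractions and sum to the duration", {
  meal <- data.frame(day = 1L, start_bin = 1L, end_bin = 12L, peak_bin = 5L,
                     start_s = 0, end_s = 6 * 3600, peak_s = 2 * 3600,
                     size = 100L, duration_s = 6 * 3600)
  m <- meal_metrics(meal)
  expect_equal(m$duration_h, 6)
  expect_equal(m$pre_peak_h, 2)
  expect_equal(m$post_peak_h, 4)

  # degenerate: peak at start
  meal$peak_s <- 0
  expect_equal(meal_metrics(meal)$pre_peak_h, 0)

  # identity on random meals
  set.seed(41)
  for (i in 1:20) {
    s <- runif(1, 0, 4e4); e <- s + runif(1, 1800, 4e4)
    meal$start_s <- s; meal$end_s <- e
    meal$peak_s <- runif(1, s, e)
    m <- meal_metrics(meal)
    expect_equal(m$duration_h, m$pre_peak_h + m$post_peak_h)
  }
})

test_that("daily_interactions sums the day's bins additively", {
  counts <- rpois(96, 3)
  b <- mk_bins(counts)
  days <- split_days(b)
  expect_equal(daily_interactions(b, days[1, ]), sum(counts[1:48]))
  expect_equal(daily_interactions(b, days[2, ]), sum(counts[49:96]))
  expect_equal(daily_interactions(mk_bins(rep(0, 48)), days[1, ]), 0L)
  # meal sizes over a day never exceed the daily total
  meals <- segment_meals(b, days[1, ], 0.1, 1)
  if (nrow(meals) > 0)
    expect_lte(sum(meals$size), daily_interactions(b, days[1, ]))
})
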