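test_that("read_flic_csv parses channels, infers dt, and validates input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ch1", "0.0,5", "0.2,7", "0.4,6"), f)
  tr <- read_flic_csv(f, layout = list(time_col = "t"))
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$values, c(5, 7, 6))
  expect_equal(tr[[1]]$dt, 0.2)

  # backwards time
  writeLines(c("t,ch1", "0.4,5", "0.2,7", "0.0,6"), f)
  expect_error(read_flic_csv(f, layout = list(time_col = "t")),
               "increasing")

  # non-numeric cell named by row/column
  writeLines(c("t,ch1", "0.0,5", "0.2,oops", "0.4,6"), f)
  expect_error(read_flic_csv(f, layout = list(time_col = "t")),
               "row 2")

  # 12 channels, shape conserved, no time column
  df <- as.data.frame(matrix(rnorm(12 * 25, 100), nrow = 25))
  utils::write.csv(df, f, row.names = FALSE)
  tr <- read_flic_csv(f)
  expect_length(tr, 12L)
  expect_true(all(vapply(tr, function(x) length(x$values), 0L) == 25L))
})

test_that("read_flic_csv forward-fills short gaps and splits long ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ch1", "5", "", "6", "7"), f)
  tr <- read_flic_csv(f)
  expect_equal(tr[[1]]$values, c(5, 5, 6, 7))
  expect_equal(attr(tr[[1]], "n_filled"), 1L)

  # gap of 60 samples (12 s) at dt 0.2 splits the channel
  vals <- c(rep("5", 10), rep("", 60), rep("7", 10))
  writeLines(c("ch1", vals), f)
  tr <- read_flic_csv(f)
  expect_length(tr, 2L)
  expect_equal(tr[[2]]$t0, 70 * 0.2)
})

test_that("moving_baseline matches the brute-force centered median", {
  # constant trace: baseline is the constant everywhere
  tr <- flic_trace(rep(100, 50))
  expect_equal(moving_baseline(tr, 2)$values, rep(100, 50))

  # isolated spike is rejected by the median
  tr <- flic_trace(c(0, 0, 0, 50, 0, 0, 0))
  expect_equal(moving_baseline(tr, 1)$values, rep(0, 7))  # 5-sample window

  # linear ramp: equals per-index truncated-window median
  tr <- flic_trace(as.numeric(0:9))
  expect_equal(moving_baseline(tr, 0.6)$values,       # 3-sample window
               oracle_baseline(tr$values, 0.2, 0.6))

  # random traces, several window widths, incl. runmed path and edges
  set.seed(11)
  for (n in c(7, 100, 900)) {
    for (w in c(0.6, 2, 24)) {
      tr <- flic_trace(rnorm(n, 100, 5) + rbinom(n, 1, 0.05) * 60)
      expect_equal(moving_baseline(tr, w)$values,
                   oracle_baseline(tr$values, 0.2, w))
    }
  }
  expect_error(moving_baseline(flic_trace(1), 0.2), "3 samples")
})

test_that("detect_interactions uses a strict threshold on the excess", {
  tr <- flic_trace(rep(100, 20))
  bl <- moving_baseline(tr, 2)
  expect_false(any(detect_interactions(tr, bl, 10)$flags))

  # excess exactly 10 is NOT an interaction ("signal over 10")
  tr$values[10] <- 110
  expect_false(any(detect_interactions(tr, moving_baseline(tr, 8), 10)$flags))

  # excess 11 is
  tr$values[10] <- 111
  fl <- detect_interactions(tr, moving_baseline(tr, 8), 10)$flags
  expect_identical(which(fl), 10L)

  expect_error(detect_interactions(tr, list(values = 1:3, t0 = 0, dt = 0.2)),
               "lengths differ")
})

test_that("raising the threshold never adds interactions", {
  set.seed(21)
  tr <- flic_trace(rnorm(500, 100, 8))
  bl <- moving_baseline(tr, 10)
  counts <- vapply(c(2, 5, 10, 20),
                   function(th) sum(detect_interactions(tr, bl, th)$flags),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("bin_interactions conserves counts and aligns bins at t0", {
  mk_inter <- function(flags, dt = 0.2) {
    structure(list(flags = flags, threshold = 10, t0 = 0, dt = dt),
              class = "interaction_series")
  }
  # all-false series
  b <- bin_interactions(mk_inter(rep(FALSE, 100)), 4)
  expect_true(all(b$counts == 0L))

  # a 30-min bin spans 9000 samples at 5 Hz
  flags <- rep(FALSE, 9000 * 2)
  flags[c(1, 9000, 9001, 12000)] <- TRUE
  b <- bin_interactions(mk_inter(flags), 1800)
  expect_equal(b$counts, c(2L, 2L))
  expect_false(b$partial_last)

  # conservation for scattered flags + partial trailing bin flagged
  set.seed(5)
  flags <- rep(FALSE, 13000)
  flags[sample(13000, 37)] <- TRUE
  b <- bin_interactions(mk_inter(flags), 1800)
  expect_equal(sum(b$counts), 37L)
  expect_true(b$partial_last)

  # width must be a positive multiple of dt
  expect_error(bin_interactions(mk_inter(rep(TRUE, 10)), 0.5001),
               "multiple of dt")
})
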