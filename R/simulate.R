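#' Configuration for the synthetic FLIC feeding experiment
#'
#' The generator emulates multi-day constant-darkness feeding records with
#' one discrete evening meal per day. Within the meal, feeding bouts arrive
#' as an inhomogeneous point process whose per-bin intensity follows a
#' ramp-peak-tail envelope; each bout contributes a run of consecutive
#' supra-threshold samples. On a sugar diet the in-meal bout intensity
#' grows multiplicatively per day and the post-peak tail lengthens so that
#' by day `n_days` the post-peak duration has grown by
#' `postpeak_growth_h` hours (default 4 h by day 10). Under closed-loop
#' light with retinal, the day-growth factors clamp to 1 from the first
#' light-triggered day onward; without retinal the light has no effect.
#'
#' Within each meal bin the bout count is drawn as 1 + Poisson(lambda - 1),
#' i.e. every in-meal bin holds at least one bout. This gives meals hard,
#' well-defined boundaries in bin space (the exact-recovery contract of the
#' generator); the bin intensities are otherwise Poisson-like.
#'
#' @param n_flies flies (one FLIC channel each). Default 20.
#' @param n_days experiment days. Default 10.
#' @param dt sample period, seconds. Default 0.2.
#' @param diet "CD" (control) or "SD" (sugar diet).
#' @param opto "off", "on_atr" (closed-loop light, retinal-fed) or
#'   "on_noatr" (light without retinal, the no-effect control).
#' @param seed integer; fixes the full stream (per-fly seeds are derived).
#' @param bin_width_s meal-model bin width, seconds. Default 1800.
#' @param meal_center_h circadian hour of the evening-meal peak bin.
#'   Default 12 (inside the default 9-15 h subjective-evening window).
#' @param pre_bins ramp bins before the peak bin. Default 3.
#' @param post_bins_base post-peak tail bins on day 1. Default 6 (3 h).
#' @param peak_rate expected bouts in the peak bin on day 1 (before the
#'   per-fly random effect). Default 14.
#' @param floor_rate expected bouts in the last tail bin. Default 4.
#' @param bout_len_mean mean bout length, samples (geometric). Default 5.
#' @param excess_min,excess_max uniform range of the per-sample signal
#'   excess above the drift during a bout, AU. Defaults 25 and 60 (well
#'   above the 10 AU detection threshold plus baseline-tracking error).
#' @param drift_step_sd per-sample SD of the baseline random walk, AU.
#'   Default 0.02.
#' @param drift_bound the walk is reflected into [-drift_bound,
#'   drift_bound]; default 2.5 AU, under 30\% of the detection threshold so
#'   detection stays exact ("hard mode" raises this).
#' @param g_size per-day multiplicative growth of in-meal bout intensity
#'   under SD. Default 1.10.
#' @param postpeak_growth_h total post-peak lengthening (hours) reached on
#'   the final day under SD. Default 4.
#' @param fly_effect_sdlog SD (log scale) of the per-fly lognormal random
#'   effect on bout intensity. Default 0.15.
#' @param controller a [controller_config()] used when `opto != "off"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_flies = 20, n_days = 10, dt = 0.2,
                       diet = c("CD", "SD"),
                       opto = c("off", "on_atr", "on_noatr"),
                       seed = 1, bin_width_s = 1800,
                       meal_center_h = 12, pre_bins = 3, post_bins_base = 6,
                       peak_rate = 14, floor_rate = 4, bout_len_mean = 5,
                       excess_min = 25, excess_max = 60,
                       drift_step_sd = 0.02, drift_bound = 2.5,
                       g_size = 1.10, postpeak_growth_h = 4,
                       fly_effect_sdlog = 0.15,
                       controller = controller_config()) {
  diet <- match.arg(diet)
  opto <- match.arg(opto)
  if (n_flies < 1 || n_days < 1) stop("need at least one fly and one day")
  if (peak_rate < 0 || floor_rate < 0 || bout_len_mean <= 0)
    stop("rates and durations must be non-negative (bout length positive)")
  if (g_size < 1) stop("g_size must be >= 1")
  if (excess_min <= 0 || excess_max < excess_min)
    stop("invalid excess amplitude range")
  cfg <- list(n_flies = as.integer(n_flies), n_days = as.integer(n_days),
              dt = dt, diet = diet, opto = opto, seed = as.integer(seed),
              bin_width_s = bin_width_s, meal_center_h = meal_center_h,
              pre_bins = as.integer(pre_bins),
              post_bins_base = as.integer(post_bins_base),
              peak_rate = peak_rate, floor_rate = floor_rate,
              bout_len_mean = bout_len_mean,
              excess_min = excess_min, excess_max = excess_max,
              drift_step_sd = drift_step_sd, drift_bound = drift_bound,
              g_size = g_size, postpeak_growth_h = postpeak_growth_h,
              fly_effect_sdlog = fly_effect_sdlog,
              controller = controller)
  class(cfg) <- "sim_config"
  cfg
}

# per-day meal envelope: relative bin indices (1-based within day) and
# expected bout counts, for growth-day index gd and per-fly effect u
.meal_envelope <- function(cfg, gd, u) {
  bins_per_day <- as.integer(round(86400 / cfg$bin_width_s))
  center <- as.integer(round(cfg$meal_center_h * 3600 / cfg$bin_width_s)) + 1L
  growth_bins_total <- round(cfg$postpeak_growth_h * 3600 / cfg$bin_width_s)
  post_bins <- cfg$post_bins_base +
    as.integer(round((gd - 1) * growth_bins_total / max(cfg$n_days - 1, 1)))
  scale <- cfg$g_size^(gd - 1)
  ramp <- if (cfg$pre_bins > 0)
    seq_len(cfg$pre_bins) / (cfg$pre_bins + 1) else numeric(0)
  floor_mult <- if (cfg$peak_rate > 0) cfg$floor_rate / cfg$peak_rate else 0
  tail_mult <- if (post_bins > 0)
    seq(0.6, floor_mult, length.out = post_bins) else numeric(0)
  mult <- c(ramp, 1, tail_mult)
  rel_bins <- (center - cfg$pre_bins):(center + post_bins)
  ok <- rel_bins >= 1L & rel_bins <= bins_per_day
  list(rel_bins = rel_bins[ok],
       lambda = cfg$peak_rate * mult[ok] * scale * u,
       peak_rel_bin = center, post_bins = post_bins)
}

#' Simulate one fly's multi-day FLIC trace with ground truth
#'
#' The raw signal is a bounded random-walk baseline drift plus, within the
#' meal bins, bouts of consecutive supra-threshold samples. Bouts are
#' placed in disjoint slots within their bin (at least one quiet sample
#' between bouts and at each bin boundary), so the per-bin ground-truth
#' bout and interaction counts are exact by construction. When an opto arm
#' is configured, the closed-loop trigger rule (signal over the trigger
#' threshold, on or after the start day) is evaluated against the known
#' drift, mirroring the device's online thresholding; with retinal, growth
#' clamps from the first triggered day.
#'
#' @param cfg a [sim_config()].
#' @param fly fly index in 1..n_flies.
#' @return list with `trace` (a [flic_trace()]) and `truth` (data.frame,
#'   one row per day: fly, day, diet, opto, meal start/end/peak bins -
#'   global 1-based - and times, n_bouts, n_interactions, post_bins,
#'   growth_day, clamped, n_light_triggers).
#' @export
simulate_fly <- function(cfg, fly) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 7919L * as.integer(fly))
  n_day_samples <- as.integer(round(86400 / cfg$dt))
  per_bin <- as.integer(round(cfg$bin_width_s / cfg$dt))
  bins_per_day <- as.integer(round(86400 / cfg$bin_width_s))
  n_total <- n_day_samples * cfg$n_days
  u <- exp(stats::rnorm(1, 0, cfg$fly_effect_sdlog))
  # bounded drift: random walk folded into [-b, b]
  b <- cfg$drift_bound
  walk <- cumsum(stats::rnorm(n_total, 0, cfg$drift_step_sd))
  drift <- abs(((walk + b) %% (4 * b)) - 2 * b) - b
  values <- drift
  opto_on <- cfg$opto != "off"
  retinal <- cfg$opto == "on_atr"
  fired <- FALSE
  clamped <- FALSE
  gd_frozen <- NA_integer_
  truth <- vector("list", cfg$n_days)
  for (d in seq_len(cfg$n_days)) {
    if (cfg$diet == "SD") {
      if (clamped) gd <- gd_frozen else gd <- d
    } else gd <- 1L
    env <- .meal_envelope(cfg, gd, u)
    day_off <- (d - 1L) * n_day_samples
    bin_counts <- integer(bins_per_day)
    n_bouts_day <- 0L
    for (k in seq_along(env$rel_bins)) {
      lam <- env$lambda[k]
      if (lam <= 0) next
      n_b <- 1L + stats::rpois(1, max(lam - 1, 0))
      n_b <- min(n_b, per_bin %/% 3L)   # keep slots >= 3 samples
      w <- per_bin %/% n_b
      bin_off <- day_off + (env$rel_bins[k] - 1L) * per_bin
      lens <- pmin(1L + stats::rgeom(n_b, 1 / cfg$bout_len_mean), w - 2L)
      lens <- pmax(lens, 1L)
      offs <- vapply(lens, function(L)
        sample.int(w - L, 1L) - 1L, integer(1))
      for (j in seq_len(n_b)) {
        idx <- bin_off + (j - 1L) * w + offs[j] + seq_len(lens[j])
        values[idx] <- drift[idx] +
          stats::runif(lens[j], cfg$excess_min, cfg$excess_max)
      }
      bin_counts[env$rel_bins[k]] <- sum(lens)
      n_bouts_day <- n_bouts_day + n_b
    }
    n_inter <- sum(bin_counts)
    # closed-loop trigger check against the known drift (online rule)
    n_trig <- 0L
    if (opto_on && d >= cfg$controller$start_day && n_inter > 0L) {
      # every bout sample exceeds the trigger threshold; at the FLIC
      # sample period the train ends as the next sample arrives, so no
      # trigger is absorbed
      n_trig <- n_inter
      if (!fired) {
        fired <- TRUE
        if (retinal) { clamped <- TRUE; gd_frozen <- gd }
      }
    }
    has_meal <- n_inter > 0L
    nz <- which(bin_counts > 0L)
    peak_rel <- if (has_meal) nz[which.max(bin_counts[nz])] else NA_integer_
    g0 <- (d - 1L) * bins_per_day
    truth[[d]] <- data.frame(
      fly = as.integer(fly), day = d, diet = cfg$diet, opto = cfg$opto,
      meal_start_bin = if (has_meal) g0 + nz[1L] else NA_integer_,
      meal_end_bin = if (has_meal) g0 + nz[length(nz)] else NA_integer_,
      peak_bin = if (has_meal) g0 + which.max(bin_counts) else NA_integer_,
      meal_start_s = if (has_meal) (g0 + nz[1L] - 1) * cfg$bin_width_s
                     else NA_real_,
      meal_end_s = if (has_meal) (g0 + nz[length(nz)]) * cfg$bin_width_s
                   else NA_real_,
      n_bouts = n_bouts_day, n_interactions = n_inter,
      post_bins = env$post_bins, growth_day = gd, clamped = clamped,
      n_light_triggers = n_trig,
      stringsAsFactors = FALSE)
  }
  list(trace = flic_trace(values, dt = cfg$dt, t0 = 0,
                          channel_id = sprintf("fly%02d", fly)),
       truth = do.call(rbind, truth))
}

#' Simulate a full FLIC experiment
#'
#' @param cfg a [sim_config()].
#' @param keep_traces keep the raw traces in the return value? They are
#'   large (432,000 samples per fly-day); set `FALSE` to collect ground
#'   truth only and regenerate traces on demand with [simulate_fly()].
#' @return list with `traces` (list of [flic_trace()] or `NULL`) and
#'   `truth` (data.frame over all flies and days).
#' @export
simulate_flic_experiment <- function(cfg, keep_traces = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  traces <- if (keep_traces) vector("list", cfg$n_flies) else NULL
  truth <- vector("list", cfg$n_flies)
  for (f in seq_len(cfg$n_flies)) {
    sim <- simulate_fly(cfg, f)
    if (keep_traces) traces[[f]] <- sim$trace
    truth[[f]] <- sim$truth
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

#' Parameters for synthetic stimulus-locked calcium transients
#'
#' The transient is a rise-decay double-exponential kernel, peak-normalized
#' and peak-aligned: the noiseless trace peaks at exactly `latency_s` after
#' the stimulus with dF/F0 amplitude `amplitude`. Condition scaling
#' reproduces the study's contrasts: on a sugar diet the sucrose-evoked
#' amplitude is multiplied by `sd_amp_mult` (default 0.5, a ~50\% decrease)
#' and the peak is delayed by `sd_latency_shift_s` (default 0.6 s); water
#' responses are condition-independent.
#'
#' @param amplitude sucrose-response peak dF/F0 (fraction). Default 0.5.
#' @param latency_s control-diet latency to peak, seconds. Default 1.0.
#' @param tau_r,tau_d rise and decay time constants, seconds (tau_r <
#'   tau_d). Defaults 0.2 and 1.0.
#' @param noise_sd per-frame Gaussian noise SD on the dF/F0 scale.
#'   Default 0.06 (SNR = amplitude / noise_sd > 8 at defaults).
#' @param sd_amp_mult sugar-diet amplitude multiplier (sucrose only).
#'   Default 0.5.
#' @param sd_latency_shift_s sugar-diet latency shift, seconds (sucrose
#'   only). Default 0.6.
#' @param water_amplitude water-response amplitude, both diets.
#'   Default 0.3.
#' @param f0 baseline fluorescence, AU. Default 100.
#' @param n_frames frames per trace. Default 100.
#' @param stim_frame stimulus-delivery frame (1-based). Default 20.
#' @param frame_period_s seconds per frame. Default 0.254.
#' @return list of class `ca_sim_params`.
#' @export
ca_sim_params <- function(amplitude = 0.5, latency_s = 1.0,
                          tau_r = 0.2, tau_d = 1.0, noise_sd = 0.06,
                          sd_amp_mult = 0.5, sd_latency_shift_s = 0.6,
                          water_amplitude = 0.3, f0 = 100,
                          n_frames = 100, stim_frame = 20,
                          frame_period_s = 0.254) {
  if (amplitude < 0 || water_amplitude < 0) stop("amplitudes must be >= 0")
  if (tau_r >= tau_d) stop("tau_r must be smaller than tau_d")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(amplitude = amplitude, latency_s = latency_s,
                 tau_r = tau_r, tau_d = tau_d, noise_sd = noise_sd,
                 sd_amp_mult = sd_amp_mult,
                 sd_latency_shift_s = sd_latency_shift_s,
                 water_amplitude = water_amplitude, f0 = f0,
                 n_frames = as.integer(n_frames),
                 stim_frame = as.integer(stim_frame),
                 frame_period_s = frame_period_s),
            class = "ca_sim_params")
}

# peak-normalized, peak-aligned rise-decay kernel: g(0) = 1 at the peak
.ca_kernel <- function(u, tau_r, tau_d) {
  s_pk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  h_pk <- exp(-s_pk / tau_d) - exp(-s_pk / tau_r)
  s <- u + s_pk
  out <- numeric(length(u))
  pos <- s > 0
  out[pos] <- (exp(-s[pos] / tau_d) - exp(-s[pos] / tau_r)) / h_pk
  out
}

#' Simulate one stimulus-locked calcium trace
#'
#' F(t) = f0 * (1 + A' * g(t - t_stim - L')) + noise, with g the
#' peak-normalized rise-decay kernel, and A', L' the condition-adjusted
#' amplitude and latency (see [ca_sim_params()]).
#'
#' @param p a [ca_sim_params()].
#' @param diet "CD" or "SD".
#' @param stimulus "sucrose" or "water".
#' @param seed RNG seed for the noise stream.
#' @param roi_id ROI label.
#' @return list with `trace` (a [calcium_trace()]) and `truth` (list:
#'   `amplitude`, `latency_s`).
#' @export
simulate_calcium_trace <- function(p, diet = c("CD", "SD"),
                                   stimulus = c("sucrose", "water"),
                                   seed = 1, roi_id = "roi1") {
  stopifnot(inherits(p, "ca_sim_params"))
  diet <- match.arg(diet)
  stimulus <- match.arg(stimulus)
  sugary <- diet == "SD" && stimulus == "sucrose"
  A <- if (stimulus == "water") p$water_amplitude else p$amplitude
  A <- A * if (sugary) p$sd_amp_mult else 1
  L <- p$latency_s + if (sugary) p$sd_latency_shift_s else 0
  set.seed(seed)
  t_rel <- (seq_len(p$n_frames) - p$stim_frame) * p$frame_period_s
  clean <- p$f0 * (1 + A * .ca_kernel(t_rel - L, p$tau_r, p$tau_d))
  noisy <- clean + stats::rnorm(p$n_frames, 0, p$noise_sd * p$f0)
  list(trace = calcium_trace(noisy, stim_frame = p$stim_frame,
                             frame_period_s = p$frame_period_s,
                             roi_id = roi_id),
       truth = list(amplitude = A, latency_s = L))
}

#' Write / read ground-truth tables
#'
#' Plain-CSV serialization of a ground-truth data.frame; the round trip
#' preserves every value.
#'
#' @param gt ground-truth data.frame (e.g. from
#'   [simulate_flic_experiment()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
truth_tables <- function(gt, path) {
  utils::write.csv(gt, path, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_tables
#' @export
read_truth_tables <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
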