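test_that("welch PSD peaks at the tone frequency on an exact 0.5-Hz grid", {
  fs <- 512
  x <- sin(2 * pi * 10 * (0:(8 * fs - 1)) / fs)
  p <- welch_psd(x, fs)
  expect_equal(p$freq[which.max(p$psd)], 10)
  expect_equal(unique(round(diff(p$freq), 12)), 0.5)
  expect_equal(min(p$freq), 0.5)           # DC dropped
  expect_equal(max(p$freq), fs / 2)
  expect_identical(p$n_segments, 15L)      # (4096 - 512)/256 + 1
})

test_that("welch PSD integrates to the signal variance (Parseval)", {
  fs <- 512
  set.seed(1)
  err <- replicate(100, {
    x <- rnorm(4 * fs)
    p <- welch_psd(x, fs)
    sum(p$psd) * p$freq[1] / stats::var(x) - 1
  })
  expect_lt(abs(mean(err)), 0.02)
  expect_lt(max(abs(err)), 0.25)
})

test_that("short segments fall back to one shortened window", {
  fs <- 512
  p <- welch_psd(sin(2 * pi * 10 * (0:255) / fs), fs, win_len = 512L)
  expect_identical(p$n_segments, 1L)
  expect_identical(p$win_len, 256L)
  expect_error(welch_psd(numeric(0), fs), "empty")
})

test_that("band_power equals the hand-computed bin mean", {
  fs <- 512
  set.seed(2)
  p <- welch_psd(rnorm(4 * fs), fs)
  sel <- p$freq >= 7.5 & p$freq <= 12
  expect_equal(band_power(p, c(7.5, 12)), mean(p$psd[sel]))
  expect_error(band_power(p, c(0.01, 0.2)), "no PSD bins")
})

test_that("band_mean_density is grid-invariant for a flat spectrum", {
  flat <- function(df, fmax) structure(
    list(freq = seq(df, fmax, by = df), psd = rep(3, fmax / df),
         n_segments = 1L, win_len = 0L), class = "psd")
  for (df in c(0.5, 2)) {
    p <- flat(df, 256)
    expect_equal(band_mean_density(p, c(7.5, 12)), 3)
    expect_equal(band_mean_density(p, c(14, 21)), 3)
  }
  # plain bin mean on the 2-Hz grid would see only bins at 8, 10, 12
  expect_error(band_mean_density(flat(2, 256), c(258, 259)), "support")
})

test_that("band power scales with amplitude squared", {
  fs <- 512
  set.seed(3)
  x <- rnorm(4 * fs)
  p1 <- band_mean_density(welch_psd(x, fs), c(7.5, 12))
  p2 <- band_mean_density(welch_psd(2 * x, fs), c(7.5, 12))
  expect_equal(p2 / p1, 4, tolerance = 1e-9)
})

simulate_small <- function(depths = NULL, n_trials = 16L, seed = 1L,
                           spike_prob = 0) {
  tr <- default_erd_truth()
  if (!is.null(depths)) {
    tr$depth <- depths
    tr$onset_s[tr$condition == "nonvocal"] <- 3.0
    tr$onset_s[tr$condition == "vocal"] <- 1.0
  }
  prof <- make_cohort(3, rng_seed = seed)[1, ]
  prof$beta_humanness_effect <- if (is.null(depths)) 0.15 else 0
  sch <- make_schedule(n_trials, rng_seed = seed, production_dur_s = 0,
                       gap_s = 2)
  raw <- simulate_eeg(prof, sch, erd = tr, rng_seed = seed,
                      artifacts = if (spike_prob > 0)
                        list(blink_rate_hz = 0, spike_prob = spike_prob,
                             spike_uv = 150) else NULL)
  preprocess(raw)$perception
}

test_that("null modulation gives no condition difference and no depth", {
  ep <- simulate_small(depths = 0, n_trials = 60L, seed = 4)
  bp <- erd(ep)
  per <- attr(bp, "per_trial")
  conds <- attr(bp, "conditions")
  fc <- c("F1", "F3", "FC1", "F2", "F4", "FC2")
  for (band in c("mu", "beta")) {
    a <- rowMeans(per[conds == "vocal", fc, band, "main"])
    b <- rowMeans(per[conds == "nonvocal", fc, band, "main"])
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)) / se, 3)
    for (cond in c("vocal", "nonvocal"))
      expect_lt(abs(erd_depth(bp, band, c("FC_L", "FC_R"), cond)), 0.15)
  }
})

test_that("vocal mu suppression is detected earlier and deeper than nonvocal", {
  ep <- simulate_small(n_trials = 48L, seed = 5)
  bp <- erd(ep)
  fc <- c("FC_L", "FC_R")
  on_v <- erd_onset(bp, "mu", fc, "vocal")
  on_n <- erd_onset(bp, "mu", fc, "nonvocal")
  expect_lt(on_v, on_n)
  d_v <- erd_depth(bp, "mu", fc, "vocal")
  d_n <- erd_depth(bp, "mu", fc, "nonvocal")
  expect_gt(d_v, d_n)
  expect_gt(d_v, 0.2)
})

test_that("band power table has the full factorial shape", {
  ep <- simulate_small(n_trials = 16L, seed = 6)
  bp <- erd(ep)
  expect_s3_class(bp, "band_power_table")
  expect_identical(nrow(bp), 2L * 2L * 6L * 7L)  # cond x band x region x window
  expect_setequal(unique(bp$region), names(default_roi()))
  expect_setequal(unique(bp$window), names(perception_windows()))
  expect_true(all(bp$n_trials == 8L))
  expect_false(any(is.na(bp$erd)))
})

test_that("erd validates baseline window and electrodes", {
  ep <- simulate_small(n_trials = 16L, seed = 7)
  expect_error(erd(ep, baseline = c(-2, 0)), "baseline window outside epoch")
  ep2 <- ep
  keep <- ep2$channel_names != "C3"
  ep2$data <- ep2$data[, keep, , drop = FALSE]
  ep2$channel_names <- ep2$channel_names[keep]
  ep2$channel_types <- ep2$channel_types[keep]
  expect_error(erd(ep2), "C3")
})

test_that("EMG band power is higher during production than perception", {
  prof <- make_cohort(3, rng_seed = 8)[1, ]
  sch <- make_schedule(12, rng_seed = 8, production_dur_s = 5, gap_s = 2)
  raw <- simulate_eeg(prof, sch, rng_seed = 8, artifacts = NULL)
  per <- epoch_recording(raw, "stimulus", c(1, 5))
  pro <- epoch_recording(raw, "go", c(1, 6))
  e_per <- emg_band_power(per, window = c(0, 5))
  e_pro <- emg_band_power(pro, window = c(0, 5))
  expect_identical(nrow(e_per), 12L)
  expect_gt(mean(e_pro$power), 2 * mean(e_per$power))
  expect_error(emg_band_power(per, band = c(10, 300)), "Nyquist")
  expect_error(emg_band_power(per, channel = "EMG9"), "not found")
})
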