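rec_from_matrix <- function(data, fs = 512, events = NULL, channels = NULL) {
  structure(list(data = data, channels = channels, fs = fs, events = events,
                 schedule = NULL, steps = character(0)),
            class = "raw_recording")
}

test_that("highpass removes DC, keeps passband, attenuates stopband", {
  fs <- 512
  t <- (0:(20 * fs - 1)) / fs
  x <- 5 + sin(2 * pi * 10 * t) + sin(2 * pi * 0.1 * t)
  rec <- rec_from_matrix(cbind(C3 = x), fs)
  out <- highpass(rec, 1)$data[, 1]
  mid <- (5 * fs):(15 * fs)               # avoid filter edges
  expect_lt(abs(mean(out[mid])), 0.05)     # DC gone
  # 10-Hz amplitude preserved within 1%
  amp10 <- 2 * abs(mean(out[mid] * exp(-2i * pi * 10 * t[mid])))
  expect_equal(amp10, 1, tolerance = 0.01)
  # 0.1-Hz component attenuated by > 30 dB
  amp01 <- 2 * abs(mean(out[mid] * exp(-2i * pi * 0.1 * t[mid])))
  expect_lt(amp01, 1 / 30)
  expect_error(highpass(rec, 300), "Nyquist")
})

test_that("mastoid re-referencing removes a shared reference exactly", {
  set.seed(2)
  n <- 2048
  common <- cumsum(rnorm(n))               # arbitrary shared signal
  sig <- rnorm(n)
  data <- cbind(C3 = sig + common, M1 = common, M2 = common)
  out <- reref_mastoids(rec_from_matrix(data))
  expect_identical(colnames(out$data), "C3")
  expect_equal(out$data[, "C3"], sig, tolerance = 1e-12)
  # asymmetric mastoids: subtracts the mean of the two
  data2 <- cbind(C3 = sig, M1 = rep(2, n), M2 = rep(4, n))
  out2 <- reref_mastoids(rec_from_matrix(data2))
  expect_equal(out2$data[, "C3"], sig - 3, tolerance = 1e-12)
  expect_error(reref_mastoids(rec_from_matrix(cbind(C3 = sig))), "missing")
})

test_that("blink regression removes blinks but spares alpha-band power", {
  fs <- 512
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  set.seed(3)
  # blink template: slow positive lobes, ~300 ms wide
  blink <- numeric(n)
  for (c0 in seq(2, 18, by = 2.5))
    blink <- blink + 80 * exp(-((t - c0)^2) / (2 * 0.08^2))
  sine <- sin(2 * pi * 10 * t)
  data <- cbind(C3 = sine + 0.4 * blink, Fpz = blink + rnorm(n, sd = 0.5))
  out <- remove_blinks(rec_from_matrix(data, fs))$data[, "C3"]
  # the slow blink contribution is mostly gone
  bt <- signal::butter(4, 4 / (fs / 2), type = "low")
  expect_lt(stats::sd(signal::filtfilt(bt, out)),
            0.25 * stats::sd(signal::filtfilt(bt, data[, "C3"])))
  # 10-Hz power preserved within 5%
  p_out <- band_mean_density(welch_psd(out, fs), c(9, 11))
  p_sine <- band_mean_density(welch_psd(sine, fs), c(9, 11))
  expect_lt(abs(p_out / p_sine - 1), 0.05)
  expect_error(remove_blinks(rec_from_matrix(cbind(C3 = sine), fs), "Fpz"),
               "not found")
})

test_that("blink regression with a zero reference is the identity", {
  fs <- 512
  set.seed(4)
  data <- cbind(C3 = rnorm(fs * 4), Fpz = numeric(fs * 4))
  rec <- rec_from_matrix(data, fs)
  expect_equal(remove_blinks(rec)$data[, "C3"], data[, "C3"])
})

test_that("epochs have the exact sample counts and recover the signal", {
  fs <- 512
  n <- 30 * fs
  set.seed(5)
  data <- cbind(C3 = rnorm(n), C4 = rnorm(n))
  ev <- data.frame(onset_s = c(3, 14), label = c("stim_vocal",
                                                 "stim_nonvocal"),
                   trial_index = 1:2)
  ev <- rbind(ev, data.frame(onset_s = c(8, 19), label = "go",
                             trial_index = 1:2))
  rec <- rec_from_matrix(data, fs, events = ev)
  per <- epoch_recording(rec, "stimulus", c(1, 5))
  expect_identical(dim(per$data), c(2L, 2L, 3072L))
  expect_identical(per$conditions, c("vocal", "nonvocal"))
  expect_equal(per$times[1], -1)
  # samples match the raw slice
  i0 <- round(3 * fs) + 1L - round(1 * fs)
  expect_equal(per$data[1, 1, ], data[i0:(i0 + 3071), "C3"])
  pro <- epoch_recording(rec, "go", c(1, 6))
  expect_identical(dim(pro$data)[3], 3584L)
  expect_identical(pro$conditions, c("vocal", "nonvocal"))
})

test_that("events at the recording edge are flagged, not dropped silently", {
  fs <- 512
  data <- cbind(C3 = rnorm(10 * fs))
  ev <- data.frame(onset_s = c(0.2, 4), label = "stim_vocal",
                   trial_index = 1:2)
  ep <- epoch_recording(rec_from_matrix(data, fs, events = ev),
                        "stimulus", c(1, 5))
  expect_identical(ep$mask$kept, c(FALSE, TRUE))
  expect_identical(ep$mask$reason[1], "edge")
})

test_that("epoching with no matching events warns and returns empty", {
  fs <- 512
  ev <- data.frame(onset_s = 2, label = "stim_vocal", trial_index = 1L)
  rec <- rec_from_matrix(cbind(C3 = rnorm(8 * fs)), fs, events = ev)
  expect_warning(ep <- epoch_recording(rec, "go", c(1, 6)), "no matching")
  expect_identical(dim(ep$data)[1], 0L)
})

make_epoch_set <- function(data, fs = 512) {
  # data: trials x channels x samples
  structure(list(
    data = data, channel_names = dimnames(data)[[2]],
    channel_types = rep("scalp", dim(data)[2]), fs = fs,
    times = seq_len(dim(data)[3]) / fs - 1,
    conditions = rep("vocal", dim(data)[1]), lock = "stimulus",
    mask = data.frame(trial_index = seq_len(dim(data)[1]),
                      kept = TRUE, reason = "none")),
    class = "epoch_set")
}

test_that("rejection keeps homogeneous epochs and catches a 150-uV spike", {
  set.seed(6)
  n_tr <- 20
  data <- array(rnorm(n_tr * 2 * 1024, sd = 10), c(n_tr, 2, 1024),
                dimnames = list(NULL, c("C3", "C4"), NULL))
  ep <- make_epoch_set(data)
  clean <- reject_epochs(ep)
  expect_true(all(clean$mask$kept))
  ep$data[7, 1, 500] <- 150
  rej <- reject_epochs(ep)
  expect_false(rej$mask$kept[7])
  expect_identical(rej$mask$reason[7], "amplitude")
  expect_identical(sum(!rej$mask$kept), 1L)
})

test_that("sub-threshold heavy-tailed epochs are caught by the statistics", {
  set.seed(7)
  n_tr <- 30
  data <- array(rnorm(n_tr * 1 * 1024, sd = 10), c(n_tr, 1, 1024),
                dimnames = list(NULL, "C3", NULL))
  # trial 11: rare large (but < 100 uV) excursions -> kurtosis/improbability
  spikes <- sample(1024, 12)
  data[11, 1, spikes] <- data[11, 1, spikes] + 90
  rej <- reject_epochs(make_epoch_set(data))
  expect_false(rej$mask$kept[11])
  expect_true(rej$mask$reason[11] %in% c("improbability", "kurtosis"))
})

test_that("raising thresholds never increases rejections", {
  set.seed(8)
  data <- array(rt(25 * 1024, df = 4) * 12, c(25, 1, 1024),
                dimnames = list(NULL, "C3", NULL))
  ep <- make_epoch_set(data)
  strict <- sum(!reject_epochs(ep, amp_uv = 60, prob_sd = 2,
                               kurt_sd = 2)$mask$kept)
  loose <- sum(!reject_epochs(ep, amp_uv = 120, prob_sd = 4,
                              kurt_sd = 4)$mask$kept)
  expect_lte(loose, strict)
})

test_that("rejection requires at least 8 usable epochs", {
  data <- array(rnorm(5 * 1 * 256), c(5, 1, 256),
                dimnames = list(NULL, "C3", NULL))
  expect_error(reject_epochs(make_epoch_set(data)), "at least 8")
})

test_that("preprocess applies the fixed order and logs every step", {
  cohort <- make_cohort(3, rng_seed = 1)
  sch <- make_schedule(12, rng_seed = 1, production_dur_s = 2, gap_s = 2)
  raw <- simulate_eeg(cohort[1, ], sch, rng_seed = 1)
  out <- preprocess(raw)
  expect_named(out, c("perception", "production", "log"))
  expect_identical(dim(out$perception$data)[3], 3072L)
  expect_identical(dim(out$production$data)[3], 3584L)
  expect_true(any(grepl("highpass", out$log)))
  expect_true(any(grepl("reref", out$log)))
  expect_true(any(grepl("remove_blinks", out$log)))
  expect_true(any(grepl("epoch\\+reject", out$log)))
  hp <- which(grepl("highpass", out$log))
  rr <- which(grepl("reref", out$log))
  bl <- which(grepl("remove_blinks", out$log))
  expect_true(hp < rr && rr < bl)
  # deterministic: same input, same mask
  out2 <- preprocess(simulate_eeg(cohort[1, ], sch, rng_seed = 1))
  expect_identical(out$perception$mask, out2$perception$mask)
})
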