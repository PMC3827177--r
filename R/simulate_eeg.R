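#' Forward simulation of multichannel EEG with condition-dependent ERD
#'
#' Each scalp channel is the sum of (i) independent 1/f background noise,
#' (ii) band-limited mu (~10 Hz) and beta (~17.5 Hz) oscillatory sources per
#' anteroposterior region, amplitude-modulated by logistic ERD envelopes
#' whose onset and depth depend on band, region and condition, and spatially
#' projected with Gaussian footprints over the montage coordinates, and
#' (iii) a common reference signal shared by all channels (removed by mastoid
#' re-referencing). An EMG channel carries 10-100 Hz bursts during production
#' windows only, and optional frontal blink deflections and >100 uV spike
#' artifacts support rejection tests. All signal amplitudes are in microvolts.
#'
#' @name simulate_eeg
NULL

# 1/f-amplitude-shaped Gaussian noise, scaled to the requested SD (uV)
one_over_f_noise <- function(n, fs, sd_uv, exponent = 1) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(nfft / 2), seq(nfft / 2 - 1, 1)) * fs / nfft
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::fft(stats::fft(stats::rnorm(nfft)) * shape, inverse = TRUE))
  x <- x[seq_len(n)]
  x * (sd_uv / stats::sd(x))
}

# noise with a Gaussian spectral envelope centered at fc (bw = full width
# at ~2 SD), scaled to the requested SD
bandlimited_noise <- function(n, fs, fc, bw, sd_uv) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(nfft / 2), seq(nfft / 2 - 1, 1)) * fs / nfft
  shape <- exp(-(f - fc)^2 / (2 * (bw / 2)^2))
  x <- Re(stats::fft(stats::fft(stats::rnorm(nfft)) * shape, inverse = TRUE))
  x <- x[seq_len(n)]
  x * (sd_uv / stats::sd(x))
}

logistic_rise <- function(t, center, ramp_s) {
  stats::plogis((t - center) / (ramp_s / 4))
}

source_centers <- function() {
  data.frame(gradient = c("FC", "CP", "PO"),
             x = 0, y = c(0.38, -0.09, -0.72))
}

#' Simulate one participant's raw EEG recording
#'
#' @param profile one row of a [make_cohort] cohort (needs
#'   `beta_humanness_effect`, `noise_scale`).
#' @param schedule a [make_schedule] trial schedule.
#' @param montage montage data.frame ([default_montage]); must contain every
#'   ROI electrode of `roi`, both mastoids, and the EMG channel.
#' @param erd ground-truth table ([default_erd_truth]).
#' @param rng_seed integer seed.
#' @param fs sampling rate in Hz (default 512).
#' @param roi ROI spec used to validate the montage (default [default_roi]).
#' @param artifacts list with `blink_rate_hz` (Poisson rate of blink events,
#'   default 0.08), `spike_prob` (per-trial probability of a >100 uV spike in
#'   the perception epoch, default 0) and `spike_uv` (default 150). Use
#'   `NULL` for a fully clean recording.
#' @param bg_sd_uv SD of the 1/f background per channel (default 10).
#' @param src_sd_uv named vector, oscillatory source SD at the footprint
#'   center (default c(mu = 15, beta = 12)).
#' @param footprint_sd Gaussian footprint SD in montage units (default 0.25).
#' @return a `raw_recording`: list with `data` (samples x channels matrix,
#'   uV), `channels` (montage), `fs`, `events` (onset_s, label, trial_index),
#'   `schedule`.
#' @export
simulate_eeg <- function(profile, schedule, montage = default_montage(),
                         erd = default_erd_truth(), rng_seed = 1L, fs = 512,
                         roi = default_roi(),
                         artifacts = list(blink_rate_hz = 0.08,
                                          spike_prob = 0, spike_uv = 150),
                         bg_sd_uv = 10, src_sd_uv = c(mu = 15, beta = 12),
                         footprint_sd = 0.25) {
  stopifnot(inherits(schedule, "trial_schedule"))
  validate_erd_truth(erd)
  missing_roi <- setdiff(unlist(roi), montage$name)
  if (length(missing_roi))
    stop("montage is missing ROI electrodes: ",
         paste(missing_roi, collapse = ", "))
  if (!all(c("M1", "M2") %in% montage$name)) stop("montage needs M1 and M2")
  if (!"EMG" %in% montage$name) stop("montage needs an EMG channel")

  dur <- max(schedule$go_s + schedule$production_dur_s) + 1.5
  n <- ceiling(dur * fs)
  tvec <- (seq_len(n) - 1) / fs
  nchan <- nrow(montage)
  scalp_idx <- which(montage$type == "scalp")
  noise_scale <- profile$noise_scale %||% 1

  with_seed(rng_seed, {
    data <- matrix(0, n, nchan, dimnames = list(NULL, montage$name))
    # independent 1/f background everywhere (mastoids carry reference noise)
    for (j in seq_len(nchan)) {
      sdj <- if (montage$type[j] == "emg") 2 else bg_sd_uv * noise_scale
      data[, j] <- one_over_f_noise(n, fs, sdj)
    }
    # common reference signal, shared by every channel; mastoid
    # re-referencing removes it exactly
    common <- one_over_f_noise(n, fs, 3)
    data <- data + common

    centers <- source_centers()
    bands <- data.frame(band = c("mu", "beta"), fc = c(10, 17.5),
                        bw = c(2, 4))
    for (bi in seq_len(nrow(bands))) {
      for (gi in seq_len(nrow(centers))) {
        band <- bands$band[bi]; grad <- centers$gradient[gi]
        src <- bandlimited_noise(n, fs, bands$fc[bi], bands$bw[bi],
                                 src_sd_uv[[band]])
        env <- rep(1, n)
        for (k in seq_len(nrow(schedule))) {
          on_k <- schedule$onset_s[k]; go_k <- schedule$go_s[k]
          prod_end <- go_k + schedule$production_dur_s[k]
          i0 <- max(1L, floor((on_k - 1.5) * fs))
          i1 <- min(n, ceiling((prod_end + 1.5) * fs))
          tt <- tvec[i0:i1]
          # perception-phase modulation (stimulus-locked)
          row <- erd[erd$band == band & erd$gradient == grad &
                       erd$condition == schedule$condition[k], ]
          if (nrow(row) == 1 && row$depth != 0) {
            d <- row$depth
            if (band == "beta" && grad == "FC" &&
                schedule$condition[k] == "vocal")
              d <- d + (profile$beta_humanness_effect %||% 0)
            d <- min(d, 0.95)
            s <- logistic_rise(tt, on_k + row$onset_s, row$ramp_s) *
              stats::plogis((go_k - tt) / 0.1)
            env[i0:i1] <- env[i0:i1] * (1 - d * s)
          }
          # production-phase modulation (Go-locked)
          rowp <- erd[erd$band == band & erd$gradient == grad &
                        erd$condition == "production", ]
          if (nrow(rowp) == 1 && rowp$depth != 0) {
            d <- min(rowp$depth, 0.95)
            s <- logistic_rise(tt, go_k + rowp$onset_s, rowp$ramp_s) *
              stats::plogis((prod_end - tt) / 0.25)
            env[i0:i1] <- env[i0:i1] * (1 - d * s)
          }
        }
        mod <- src * env
        dx <- montage$x[scalp_idx] - centers$x[gi]
        dy <- montage$y[scalp_idx] - centers$y[gi]
        gain <- exp(-(dx^2 + dy^2) / (2 * footprint_sd^2))
        data[, scalp_idx] <- data[, scalp_idx] + outer(mod, gain)
      }
    }

    # EMG bursts during production windows only
    emg_j <- which(montage$name == "EMG")
    burst <- bandlimited_noise(n, fs, 55, 90, 30)
    emg_env <- rep(0, n)
    for (k in seq_len(nrow(schedule))) {
      go_k <- schedule$go_s[k]
      prod_end <- go_k + schedule$production_dur_s[k]
      i0 <- max(1L, floor((go_k - 0.5) * fs)); i1 <- min(n, ceiling((prod_end + 0.5) * fs))
      tt <- tvec[i0:i1]
      emg_env[i0:i1] <- pmax(emg_env[i0:i1],
                             logistic_rise(tt, go_k + 0.3, 0.3) *
                               stats::plogis((prod_end - tt) / 0.15))
    }
    data[, emg_j] <- data[, emg_j] + burst * emg_env

    # artifacts
    if (!is.null(artifacts)) {
      blink_rate <- artifacts$blink_rate_hz %||% 0
      if (blink_rate > 0) {
        n_blinks <- stats::rpois(1, blink_rate * dur)
        if (n_blinks > 0) {
          times <- sort(stats::runif(n_blinks, 0.5, dur - 0.5))
          blen <- round(0.25 * fs)
          tpl <- 0.5 - 0.5 * cos(2 * pi * seq_len(blen) / (blen + 1))
          bg_gain <- exp(-((montage$x[scalp_idx])^2 +
                             (montage$y[scalp_idx] - 0.9)^2) / (2 * 0.18^2))
          for (tb in times) {
            i0 <- round(tb * fs)
            amp <- stats::runif(1, 60, 110)
            seg <- i0:(i0 + blen - 1L)
            data[seg, scalp_idx] <- data[seg, scalp_idx] +
              outer(amp * tpl, bg_gain)
          }
        }
      }
      spike_prob <- artifacts$spike_prob %||% 0
      if (spike_prob > 0) {
        spike_uv <- artifacts$spike_uv %||% 150
        hit <- stats::runif(nrow(schedule)) < spike_prob
        slen <- round(0.03 * fs)
        tpl <- spike_uv * (1 - abs(seq(-1, 1, length.out = slen)))
        for (k in which(hit)) {
          ch <- sample(scalp_idx, 1)
          t0 <- schedule$onset_s[k] + stats::runif(1, -0.8, 4.7)
          i0 <- round(t0 * fs)
          data[i0:(i0 + slen - 1L), ch] <- data[i0:(i0 + slen - 1L), ch] +
            sample(c(-1, 1), 1) * tpl
        }
      }
    }

    events <- rbind(
      data.frame(onset_s = schedule$onset_s,
                 label = paste0("stim_", schedule$condition),
                 trial_index = schedule$trial),
      data.frame(onset_s = schedule$go_s, label = "go",
                 trial_index = schedule$trial)
    )
    events <- events[order(events$onset_s), ]
    rownames(events) <- NULL
    structure(list(data = data, channels = montage, fs = fs,
                   events = events, schedule = schedule),
              class = "raw_recording")
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %.1f s @ %g Hz, %d events\n",
              ncol(x$data), nrow(x$data) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}
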