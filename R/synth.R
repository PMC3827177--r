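#' Audio synthesis of melodic stimuli
#'
#' Two renditions of each melody are used in the imitation task: a non-vocal
#' timbre (band-limited triangle wave: odd partials 1, 3, 5, 7 with
#' amplitudes 1/k^2 and alternating sign, i.e. the fundamental plus the next
#' three harmonics of a triangle wave with decreasing intensity) and a
#' vocal-like timbre with controlled cycle-level jitter, shimmer and slow f0
#' drift matching the acoustic descriptors of sung notes.
#'
#' @name synthesis
NULL

new_audio_clip <- function(samples, sample_rate, note_boundaries) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 note_boundaries = note_boundaries),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s @ %d Hz, %d notes, peak %.3f\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              nrow(x$note_boundaries), max(abs(x$samples))))
  invisible(x)
}

# linear rise/fall envelope, ramp length in samples
linear_envelope <- function(n, ramp) {
  env <- rep(1, n)
  if (ramp > 0) {
    r <- min(ramp, floor(n / 2))
    env[seq_len(r)] <- seq(0, 1, length.out = r + 1)[-1]
    env[n - seq_len(r) + 1] <- seq(0, 1, length.out = r + 1)[-1]
  }
  env
}

#' Synthesize a melody with the non-vocal triangle-wave timbre
#'
#' Each 750-ms note is an additive sum of `n_partials` odd harmonics
#' (k = 1, 3, 5, ...) with strictly decreasing amplitudes 1/k^2 and
#' alternating sign (a band-limited triangle wave), shaped by a linear
#' 5-ms rise/fall envelope. The output is peak-normalized. Synthesis is
#' deterministic: identical inputs give identical samples.
#'
#' @param m a [melody].
#' @param sr sample rate in Hz (default 44100).
#' @param note_dur note duration in seconds (default 0.750).
#' @param n_partials number of odd partials (default 4, i.e. k = 1,3,5,7).
#' @param env_ms rise/fall time of the amplitude envelope in ms (default 5).
#' @return an `audio_clip` with per-note boundaries.
#' @export
synth_triangle <- function(m, sr = 44100, note_dur = 0.750,
                           n_partials = 4L, env_ms = 5) {
  stopifnot(inherits(m, "melody"))
  if (length(m$pitches) == 0) stop("melody has no notes")
  freqs <- melody_freqs(m)
  kmax <- 2L * n_partials - 1L
  if (any(freqs * kmax >= sr / 2))
    stop("highest partial would alias: reduce n_partials or frequencies")
  n <- round(note_dur * sr)
  t <- (seq_len(n) - 1) / sr
  env <- linear_envelope(n, round(env_ms / 1000 * sr))
  ks <- 2 * seq_len(n_partials) - 1
  amps <- (-1)^(seq_len(n_partials) - 1) / ks^2
  notes <- lapply(freqs, function(f) {
    x <- numeric(n)
    for (j in seq_along(ks)) x <- x + amps[j] * sin(2 * pi * ks[j] * f * t)
    x * env
  })
  samples <- unlist(notes, use.names = FALSE)
  samples <- samples / max(abs(samples))
  bounds <- data.frame(
    note_index = seq_along(freqs),
    start_s = (seq_along(freqs) - 1) * note_dur,
    end_s = seq_along(freqs) * note_dur,
    target_semitone = m$pitches
  )
  new_audio_clip(samples, sr, bounds)
}

#' Perturbation parameters for the vocal-like timbre
#'
#' Defaults are the measured acoustic descriptors of the sung stimuli:
#' jitter 0.29%, shimmer 1.35%, slow f0 drift SD 8.5 cents, median note
#' duration 0.738 s.
#'
#' @param jitter_pct expected cycle-to-cycle local jitter in percent.
#' @param shimmer_pct expected cycle-amplitude local shimmer in percent.
#' @param f0_sd_cents stationary SD of the slow log-f0 drift in cents.
#' @param note_dur_s note duration in seconds.
#' @return a `perturbation_params` list.
#' @export
perturbation_params <- function(jitter_pct = 0.29, shimmer_pct = 1.35,
                                f0_sd_cents = 8.5, note_dur_s = 0.738) {
  stopifnot(jitter_pct >= 0, shimmer_pct >= 0, f0_sd_cents >= 0,
            note_dur_s > 0)
  structure(list(jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
                 f0_sd_cents = f0_sd_cents, note_dur_s = note_dur_s),
            class = "perturbation_params")
}

#' Synthesize a melody with a vocal-like perturbed timbre
#'
#' A stand-in for sung renditions: the same odd-partial additive timbre as
#' [synth_triangle], but with (i) cycle-level Gaussian period perturbation
#' scaled so the expected local jitter equals `p$jitter_pct` (the Gaussian SD
#' is jitter_pct * sqrt(pi)/2, since local jitter of iid perturbations is
#' E|d_i - d_{i-1}| = 2 sigma / sqrt(pi)); (ii) cycle-amplitude Gaussian
#' shimmer scaled the same way; (iii) a slow Ornstein-Uhlenbeck log-f0 drift
#' with stationary SD `p$f0_sd_cents` cents (time constant 0.2 s). Per-cycle
#' gains switch at upward zero crossings so no clicks are introduced.
#'
#' @param m a [melody].
#' @param p [perturbation_params].
#' @param rng_seed integer seed; same seed gives identical audio.
#' @param sr sample rate (default 44100).
#' @param n_partials,env_ms as in [synth_triangle].
#' @return an `audio_clip`.
#' @export
synth_vocal_like <- function(m, p = perturbation_params(), rng_seed = 1L,
                             sr = 44100, n_partials = 4L, env_ms = 5) {
  stopifnot(inherits(m, "melody"), inherits(p, "perturbation_params"))
  if (length(m$pitches) == 0) stop("melody has no notes")
  freqs <- melody_freqs(m)
  kmax <- 2L * n_partials - 1L
  if (any(freqs * kmax >= sr / 2))
    stop("highest partial would alias: reduce n_partials or frequencies")
  dur <- p$note_dur_s
  n <- round(dur * sr)
  env <- linear_envelope(n, round(env_ms / 1000 * sr))
  ks <- 2 * seq_len(n_partials) - 1
  amps <- (-1)^(seq_len(n_partials) - 1) / ks^2
  sig_j <- p$jitter_pct / 100 * sqrt(pi) / 2
  sig_s <- p$shimmer_pct / 100 * sqrt(pi) / 2
  tau <- 0.2  # OU time constant (s) of the slow f0 drift

  notes <- with_seed(rng_seed, lapply(freqs, function(f0) {
    n_cyc <- ceiling(dur * f0 * 1.2) + 4L
    # OU drift in cents, sampled per cycle (cycle spacing ~ 1/f0)
    dt <- 1 / f0
    a <- exp(-dt / tau)
    drift <- numeric(n_cyc)
    drift[1] <- stats::rnorm(1, 0, p$f0_sd_cents)
    if (p$f0_sd_cents > 0 && n_cyc > 1) {
      innov <- stats::rnorm(n_cyc - 1, 0, p$f0_sd_cents * sqrt(1 - a^2))
      for (i in 2:n_cyc) drift[i] <- a * drift[i - 1] + innov[i - 1]
    }
    periods <- (1 / (f0 * 2^(drift / 1200))) *
      pmax(0.5, 1 + sig_j * stats::rnorm(n_cyc))
    gains <- pmax(0, 1 + sig_s * stats::rnorm(n_cyc))
    ends <- cumsum(periods)
    starts <- c(0, ends[-n_cyc])
    t <- (seq_len(n) - 1) / sr
    cyc <- findInterval(t, ends) + 1L          # cycle index per sample
    cyc[cyc > n_cyc] <- n_cyc
    phase <- (cyc - 1) + (t - starts[cyc]) / periods[cyc]
    x <- numeric(n)
    for (j in seq_along(ks)) x <- x + amps[j] * sin(2 * pi * ks[j] * phase)
    x * gains[cyc] * env
  }))
  samples <- unlist(notes, use.names = FALSE)
  samples <- samples / max(abs(samples))
  bounds <- data.frame(
    note_index = seq_along(freqs),
    start_s = (seq_along(freqs) - 1) * dur,
    end_s = seq_along(freqs) * dur,
    target_semitone = m$pitches
  )
  new_audio_clip(samples, sr, bounds)
}

#' Normalize a set of clips to equal intensity (RMS)
#'
#' Every clip is rescaled to the same root-mean-square amplitude; within-clip
#' dynamics are preserved (pure rescaling).
#'
#' @param clips list of `audio_clip`s.
#' @param target_rms target RMS in full-scale units (default 0.1).
#' @return list of rescaled `audio_clip`s.
#' @export
normalize_intensity <- function(clips, target_rms = 0.1) {
  if (length(clips) == 0) stop("empty clip list")
  lapply(clips, function(cl) {
    stopifnot(inherits(cl, "audio_clip"))
    r <- sqrt(mean(cl$samples^2))
    if (r == 0) stop("cannot normalize an all-zero clip")
    cl$samples <- cl$samples * (target_rms / r)
    cl
  })
}
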