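#' Synthetic cohort construction
#'
#' A synthetic study cohort with known ground truth: each participant has a
#' vocal inaccuracy (the mean absolute interval deviation their sung
#' responses will show, in cents) and a "humanness" effect size (extra
#' fronto-central beta ERD depth when listening to vocal melodies). The two
#' are coupled through a Gaussian copula so that the population Spearman
#' correlation between them equals a configurable target, enabling recovery
#' tests of the accuracy-ERD correlation analysis.
#'
#' @name synthetic_cohort
NULL

#' Default ERD/ERS ground truth table
#'
#' One row per (band, gradient, condition) with the onset (s, relative to the
#' locking event: stimulus onset for perception conditions, Go signal for
#' production), fractional amplitude depth (negative = synchronization), and
#' logistic ramp duration. Defaults encode the study phenomena: fronto-central
#' ERD earlier (1 s vs 3 s post-onset) and deeper for vocal than non-vocal
#' listening in both bands, mu ERS over posterior regions during listening,
#' and production ERD that is gradient-uniform in mu but centro-parietally
#' dominant in beta.
#'
#' @return data.frame of class `erd_truth`.
#' @export
default_erd_truth <- function() {
  tr <- rbind(
    data.frame(band = "mu", gradient = c("FC", "FC", "CP", "CP", "PO", "PO"),
               condition = rep(c("vocal", "nonvocal"), 3),
               onset_s = c(1.0, 3.0, 0.5, 0.5, 0.5, 0.5),
               depth = c(0.45, 0.30, -0.15, -0.15, -0.20, -0.20),
               ramp_s = 0.5),
    data.frame(band = "mu", gradient = c("FC", "CP", "PO"),
               condition = "production",
               onset_s = 0.3, depth = c(0.35, 0.35, 0.30), ramp_s = 0.5),
    data.frame(band = "beta", gradient = c("FC", "FC", "CP", "CP", "PO", "PO"),
               condition = rep(c("vocal", "nonvocal"), 3),
               onset_s = c(1.0, 3.0, 1.0, 3.0, 0.5, 0.5),
               depth = c(0.35, 0.20, 0.05, 0.05, 0.0, 0.0),
               ramp_s = 0.5),
    data.frame(band = "beta", gradient = c("FC", "CP", "PO"),
               condition = "production",
               onset_s = 0.3, depth = c(0.15, 0.40, 0.02), ramp_s = 0.5)
  )
  class(tr) <- c("erd_truth", "data.frame")
  validate_erd_truth(tr)
  tr
}

validate_erd_truth <- function(tr) {
  need <- c("band", "gradient", "condition", "onset_s", "depth", "ramp_s")
  stopifnot(all(need %in% names(tr)))
  for (b in unique(tr$band)) {
    fc <- tr[tr$band == b & tr$gradient == "FC", ]
    dv <- fc$depth[fc$condition == "vocal"]
    dn <- fc$depth[fc$condition == "nonvocal"]
    ov <- fc$onset_s[fc$condition == "vocal"]
    on <- fc$onset_s[fc$condition == "nonvocal"]
    if (length(dv) && length(dn) && (dv < dn || ov >= on))
      stop("erd truth must have deeper and earlier fronto-central ERD for ",
           "vocal than non-vocal listening")
  }
  invisible(tr)
}

#' Generate a trial schedule
#'
#' 120 trials by default, 60 per condition in randomized order. The Go
#' signal follows each 3.75-s stimulus onset by exactly 5 s, so five 1-s
#' analysis windows tile the span from stimulus onset to the Go signal; a
#' 5-s production window follows the Go signal. Inter-trial gaps keep the
#' [-1, +5] s perception and [-1, +6] s production epochs of adjacent trials
#' from overlapping.
#'
#' @param n_trials total trials (even; half vocal, half non-vocal).
#' @param rng_seed seed for the condition order.
#' @param stim_dur_s stimulus duration (default 3.75).
#' @param go_delay_s Go signal latency after stimulus onset (default 5).
#' @param production_dur_s production window (default 5).
#' @param gap_s silent gap after the production window (default 2.5).
#' @param t_start_s onset of the first trial (default 2).
#' @return data.frame of class `trial_schedule`: trial, condition, onset_s,
#'   go_s, stim_dur_s, production_dur_s.
#' @export
make_schedule <- function(n_trials = 120L, rng_seed = 1L, stim_dur_s = 3.75,
                          go_delay_s = 5, production_dur_s = 5, gap_s = 2.5,
                          t_start_s = 2) {
  stopifnot(n_trials %% 2 == 0, gap_s >= 2)
  cond <- with_seed(rng_seed,
                    sample(rep(c("vocal", "nonvocal"), n_trials / 2)))
  spacing <- go_delay_s + production_dur_s + gap_s
  onset <- t_start_s + (seq_len(n_trials) - 1) * spacing
  sch <- data.frame(trial = seq_len(n_trials), condition = cond,
                    onset_s = onset, go_s = onset + go_delay_s,
                    stim_dur_s = stim_dur_s,
                    production_dur_s = production_dur_s)
  class(sch) <- c("trial_schedule", "data.frame")
  sch
}

#' Generate participant profiles with coupled inaccuracy and beta effect
#'
#' Vocal inaccuracy is log-normal (median `inaccuracy_median` cents) and the
#' fronto-central beta humanness effect is normal (`effect_mean`,
#' `effect_sd`); the two are joined by a Gaussian copula whose correlation is
#' set to `2 * sin(pi * coupling_rho / 6)` so the population Spearman
#' correlation equals `coupling_rho`.
#'
#' @param n_participants cohort size (default 19).
#' @param rng_seed integer seed.
#' @param coupling_rho target Spearman correlation between inaccuracy and
#'   effect, in [-1, 1] (default 0.49).
#' @param erd ground-truth table (validated; default [default_erd_truth]).
#' @param inaccuracy_median median vocal inaccuracy in cents (default 52).
#' @param inaccuracy_log_sd log-scale SD of inaccuracy (default 0.35).
#' @param effect_mean,effect_sd beta humanness effect distribution
#'   (fractional depth units; defaults 0.15 and 0.06).
#' @param noise_scale multiplier on background EEG noise (default 1).
#' @return data.frame of class `cohort`: id, tessitura, vocal_inaccuracy_cents,
#'   beta_humanness_effect, noise_scale.
#' @export
make_cohort <- function(n_participants = 19L, rng_seed = 1L,
                        coupling_rho = 0.49, erd = default_erd_truth(),
                        inaccuracy_median = 52, inaccuracy_log_sd = 0.35,
                        effect_mean = 0.15, effect_sd = 0.06,
                        noise_scale = 1) {
  if (n_participants < 3) stop("need at least 3 participants")
  if (abs(coupling_rho) > 1) stop("|coupling_rho| must be <= 1")
  validate_erd_truth(erd)
  r <- 2 * sin(pi * coupling_rho / 6)
  prof <- with_seed(rng_seed, {
    z1 <- stats::rnorm(n_participants)
    z2 <- if (abs(r) >= 1) sign(r) * z1 else
      r * z1 + sqrt(1 - r^2) * stats::rnorm(n_participants)
    data.frame(
      id = sprintf("P%02d", seq_len(n_participants)),
      tessitura = rep_len(c("female", "male"), n_participants),
      vocal_inaccuracy_cents = inaccuracy_median * exp(inaccuracy_log_sd * z1),
      beta_humanness_effect = effect_mean + effect_sd * z2,
      noise_scale = noise_scale
    )
  })
  class(prof) <- c("cohort", "data.frame")
  prof
}

#' Simulate one participant's sung responses as an f0 track
#'
#' Note-level pitch errors are Gaussian with SD
#' `inaccuracy * sqrt(pi) / 2` cents so that the mean absolute interval
#' deviation (difference of two adjacent note errors, folded) converges to
#' the profile's `vocal_inaccuracy_cents`. A global transposition offset
#' (SD 30 cents) is added; interval-based scoring is invariant to it.
#'
#' @param profile one row of a [make_cohort] data.frame (or a list with
#'   `vocal_inaccuracy_cents`).
#' @param target target [melody].
#' @param rng_seed integer seed (same seed, same track).
#' @param note_dur produced note duration in seconds (default 0.75).
#' @return an `f0_track` with known note boundaries.
#' @export
simulate_sung_response <- function(profile, target, rng_seed,
                                   note_dur = 0.75) {
  stopifnot(inherits(target, "melody"))
  inacc <- profile$vocal_inaccuracy_cents
  n <- length(target$pitches)
  with_seed(rng_seed, {
    offset <- stats::rnorm(1, 0, 30)
    eps <- stats::rnorm(n, 0, inacc * sqrt(pi) / 2)
    f0 <- melody_freqs(target) * 2^((offset + eps) / 1200)
    tr <- f0_track_from_notes(f0, note_dur = note_dur)
    tr$note_boundaries$target_semitone <- target$pitches
    tr
  })
}
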