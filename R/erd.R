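#' Event-related desynchronization (baseline-subtracted band power)
#'
#' The study's core quantity: per trial, electrode and analysis window, mean
#' Welch band power minus the band power of the [-0.5, 0] s pre-event
#' baseline; averaged over trials within condition, then over the electrodes
#' of each region of interest. Negative values indicate desynchronization
#' (ERD), positive values synchronization (ERS). Note this subtractive
#' measure is not scale-invariant: doubling the signal amplitude quadruples
#' both terms.
#'
#' @name spectral_erd
NULL

#' Default analysis windows
#'
#' Perception: the 0-3.5 s main window, five 1-s time-course windows tiling
#' stimulus onset to the Go signal, and the 0.25-3 s window used for the
#' accuracy correlation. Production: 0-5 s after the Go signal.
#'
#' @return named list of c(start, end) windows in seconds.
#' @export
perception_windows <- function() {
  list(main = c(0, 3.5),
       w1 = c(0, 1), w2 = c(1, 2), w3 = c(2, 3), w4 = c(3, 4), w5 = c(4, 5),
       effect = c(0.25, 3))
}

#' @rdname perception_windows
#' @export
production_windows <- function() list(main = c(0, 5))

#' Default frequency bands
#' @return named list: mu 7.5-12 Hz, beta 14-21 Hz.
#' @export
default_bands <- function() list(mu = c(7.5, 12), beta = c(14, 21))

# band power of one sample segment at the analysis resolution
segment_band_power <- function(seg, fs, bands, win_len = 512L) {
  p <- welch_psd(seg, fs, win_len = win_len)
  vapply(bands, function(b) band_mean_density(p, b), numeric(1))
}

#' Compute baseline-subtracted band power per ROI and window
#'
#' For each surviving trial and ROI electrode, band power in every analysis
#' window (512-point Hann Welch segments, 50% overlap, 0.5-Hz grid) minus the
#' baseline band power (single 256-point Hann periodogram on [-0.5, 0] s,
#' 2-Hz bins, averaged over the same band). Trial values are averaged within
#' condition, then across each region's electrodes.
#'
#' @param ep an `epoch_set` (only kept epochs are used).
#' @param roi named list of electrode vectors (default [default_roi]).
#' @param bands named list of c(lo, hi) bands (default [default_bands]).
#' @param windows named list of c(start, end) analysis windows in seconds
#'   (default depends on the epoch lock).
#' @param baseline baseline window (default c(-0.5, 0)).
#' @return data.frame of class `band_power_table`: condition, band, region,
#'   window, erd (uV^2/Hz), baseline (uV^2/Hz), n_trials. Cells with no
#'   surviving trials carry NA, not zero. The per-trial, per-electrode values
#'   are attached as `attr(, "per_trial")`.
#' @export
erd <- function(ep, roi = default_roi(), bands = default_bands(),
                windows = NULL, baseline = c(-0.5, 0)) {
  stopifnot(inherits(ep, "epoch_set"))
  if (is.null(windows))
    windows <- if (identical(ep$lock, "go")) production_windows()
      else perception_windows()
  if (baseline[1] < min(ep$times) || baseline[2] > max(ep$times) + 1e-9)
    stop("baseline window outside epoch")
  electrodes <- unique(unlist(roi))
  missing_el <- setdiff(electrodes, ep$channel_names)
  if (length(missing_el))
    stop("epochs lack ROI electrodes: ", paste(missing_el, collapse = ", "))
  kept <- which(ep$mask$kept)
  fs <- ep$fs
  base_idx <- which(ep$times >= baseline[1] - 1e-9 & ep$times < baseline[2] - 1e-9)
  win_idx <- lapply(windows, function(w)
    which(ep$times >= w[1] - 1e-9 & ep$times < w[2] - 1e-9))
  el_idx <- match(electrodes, ep$channel_names)
  nb <- length(bands); nw <- length(windows)

  # per-trial x electrode x band x window baseline-subtracted power
  per <- array(NA_real_, c(length(kept), length(electrodes), nb, nw),
               dimnames = list(NULL, electrodes, names(bands), names(windows)))
  per_abs <- per
  basev <- array(NA_real_, c(length(kept), length(electrodes), nb))
  for (ti in seq_along(kept)) {
    tr <- kept[ti]
    for (ei in seq_along(electrodes)) {
      x <- ep$data[tr, el_idx[ei], ]
      pb <- welch_psd(x[base_idx], fs, win_len = length(base_idx),
                      overlap_frac = 0, nfft = length(base_idx))
      base_bp <- vapply(bands, function(b) band_mean_density(pb, b),
                        numeric(1))
      basev[ti, ei, ] <- base_bp
      for (wi in seq_len(nw)) {
        bp <- segment_band_power(x[win_idx[[wi]]], fs, bands)
        per_abs[ti, ei, , wi] <- bp
        per[ti, ei, , wi] <- bp - base_bp
      }
    }
  }

  conds <- ep$conditions[kept]
  rows <- list()
  for (cn in unique(conds)) {
    sel <- conds == cn
    for (bi in seq_len(nb)) for (wi in seq_len(nw)) {
      # trials -> electrodes averaging order
      m <- per[sel, , bi, wi, drop = FALSE]
      dim(m) <- c(sum(sel), length(electrodes))
      el_means <- stats::setNames(colMeans(m), electrodes)
      for (rn in names(roi)) {
        em <- el_means[roi[[rn]]]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, band = names(bands)[bi], region = rn,
          window = names(windows)[wi],
          erd = if (sum(sel) > 0) mean(em) else NA_real_,
          baseline = NA_real_, n_trials = sum(sel))
      }
    }
  }
  out <- do.call(rbind, rows)
  # baseline band power per condition/band/region (for fractional-drop use)
  for (i in seq_len(nrow(out))) {
    sel <- conds == out$condition[i]
    bi <- match(out$band[i], names(bands))
    m <- basev[sel, , bi, drop = FALSE]
    dim(m) <- c(sum(sel), length(electrodes))
    em <- stats::setNames(colMeans(m), electrodes)
    out$baseline[i] <- mean(em[roi[[out$region[i]]]])
  }
  attr(out, "per_trial") <- per
  attr(out, "per_trial_abs") <- per_abs
  attr(out, "conditions") <- conds
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Estimate ERD onset from time-course windows
#'
#' The onset is the start time of the first time-course window whose
#' condition-mean ERD (averaged over the given regions) lies below
#' `-z_crit` standard errors of zero, computed across trials.
#'
#' @param bp a `band_power_table` from [erd] with time-course windows.
#' @param band band name (e.g. "beta").
#' @param regions region names averaged together (e.g. c("FC_L", "FC_R")).
#' @param condition condition name.
#' @param windows names of the time-course windows, in temporal order.
#' @param window_starts start times matching `windows`.
#' @param z_crit criterion in SE units (default 2).
#' @return onset time in seconds, or `Inf` when no window reaches criterion.
#' @export
erd_onset <- function(bp, band, regions, condition,
                      windows = paste0("w", 1:5),
                      window_starts = 0:4, z_crit = 2) {
  per <- attr(bp, "per_trial")
  conds <- attr(bp, "conditions")
  if (is.null(per)) stop("band_power_table lacks per-trial values")
  roi_names <- dimnames(per)[[2]]
  els <- roi_names[roi_names %in% unlist(regions_to_electrodes(bp, regions))]
  sel <- conds == condition
  for (i in seq_along(windows)) {
    v <- per[sel, els, band, windows[i], drop = FALSE]
    trial_means <- rowMeans(v, dims = 1)
    m <- mean(trial_means)
    se <- stats::sd(trial_means) / sqrt(length(trial_means))
    if (m < -z_crit * se) return(window_starts[i])
  }
  Inf
}

#' Estimate the fractional ERD band-power drop
#'
#' Ratio-based depth estimate: one minus the ratio of mean band power in a
#' window after the desynchronization to mean band power in a window before
#' it, both measured at the analysis resolution (512-point Welch). Because
#' numerator and denominator share the same spectral window, taper leakage
#' of narrowband sources cancels; the subtractive ERD against the short
#' 256-point baseline periodogram does not have this property, so depth
#' should be read from this estimate, not from `-erd / baseline`. For a
#' source whose amplitude is reduced by a factor (1 - d), the expected value
#' is 1 - (1 - d)^2, diluted toward zero by broadband background power in
#' the band.
#'
#' @param bp a `band_power_table` from [erd] with time-course windows.
#' @param band band name.
#' @param regions region names (or electrode names) averaged together.
#' @param condition condition name.
#' @param pre_window name of a window entirely before the expected onset.
#' @param post_window name of a window with the reduction fully established.
#' @return fractional band-power drop (positive = desynchronization).
#' @export
erd_depth <- function(bp, band, regions, condition,
                      pre_window = "w1", post_window = "w3") {
  per <- attr(bp, "per_trial_abs")
  conds <- attr(bp, "conditions")
  if (is.null(per)) stop("band_power_table lacks per-trial band powers")
  roi_names <- dimnames(per)[[2]]
  els <- roi_names[roi_names %in% unlist(regions_to_electrodes(bp, regions))]
  sel <- conds == condition
  if (!any(sel)) stop("no trials in condition '", condition, "'")
  pre <- per[sel, els, band, pre_window, drop = FALSE]
  post <- per[sel, els, band, post_window, drop = FALSE]
  1 - mean(post) / mean(pre)
}

# map region names to electrodes using the table's roi (stored implicitly via
# default_roi unless regions are electrode names already)
regions_to_electrodes <- function(bp, regions) {
  roi <- default_roi()
  lapply(regions, function(r) if (r %in% names(roi)) roi[[r]] else r)
}

#' Per-trial EMG band power
#'
#' Welch band power of the EMG channel per epoch over an analysis window,
#' without baseline subtraction.
#'
#' @param ep an `epoch_set` containing the EMG channel.
#' @param channel EMG channel name (default "EMG").
#' @param band frequency band (default c(10, 100) Hz).
#' @param window analysis window in seconds (default the whole post-lock
#'   span).
#' @return data.frame: trial_index, condition, power (uV^2/Hz), for kept
#'   trials.
#' @export
emg_band_power <- function(ep, channel = "EMG", band = c(10, 100),
                           window = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  if (!channel %in% ep$channel_names) stop("EMG channel not found: ", channel)
  if (band[2] >= ep$fs / 2) stop("band extends beyond Nyquist")
  if (is.null(window)) window <- c(0, max(ep$times))
  idx <- which(ep$times >= window[1] - 1e-9 & ep$times < window[2] - 1e-9)
  j <- match(channel, ep$channel_names)
  kept <- which(ep$mask$kept)
  pow <- vapply(kept, function(tr) {
    p <- welch_psd(ep$data[tr, j, idx], ep$fs)
    band_power(p, band)
  }, numeric(1))
  data.frame(trial_index = ep$mask$trial_index[kept],
             condition = ep$conditions[kept], power = pow)
}
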