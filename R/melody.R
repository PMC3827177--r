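#' Melodic stimulus generation
#'
#' Five-note isochronous melodies built by pseudo-random concatenation of
#' pitches within a singer's comfortable range (tessitura), with small
#' melodic intervals favored over large ones and no interval exceeding
#' 10 semitones. Pitches are integer semitones relative to C4 = 0
#' (A4 = 440 Hz, equal temperament): the female tessitura spans G3..G4
#' (-5..+7), the male tessitura C3..C4 (-12..0, i.e. the female range
#' transposed down 7 semitones).
#'
#' @name melody
NULL

tessitura_range <- function(tessitura) {
  switch(tessitura,
    female = c(-5L, 7L),   # G3 (196.00 Hz) .. G4 (392.00 Hz)
    male   = c(-12L, 0L),  # C3 (130.81 Hz) .. C4 (261.63 Hz)
    stop("unknown tessitura: ", tessitura, " (use 'female' or 'male')")
  )
}

#' Generate a random five-note melody
#'
#' Interval magnitudes are drawn from a truncated geometric distribution on
#' 0..`max_interval` (parameter `small_interval_bias`, the geometric success
#' probability: larger values favor smaller intervals), with random sign;
#' candidate notes falling outside the tessitura are rejected and resampled.
#' Tone repetition (interval 0) is allowed.
#'
#' @param rng_seed integer seed; the same seed reproduces the same melody.
#' @param tessitura `"female"` (G3..G4) or `"male"` (C3..C4).
#' @param n_notes number of notes (default 5).
#' @param max_interval largest allowed absolute interval in semitones
#'   (default 10).
#' @param small_interval_bias geometric parameter in (0, 1] controlling the
#'   preference for small intervals (default 0.35).
#' @param id optional label.
#' @return an object of class `melody`: list with `pitches` (semitones
#'   relative to C4), `tessitura`, `id`.
#' @examples
#' m <- generate_melody(1, "female")
#' max(abs(diff(m$pitches))) <= 10
#' @export
generate_melody <- function(rng_seed, tessitura = c("female", "male"),
                            n_notes = 5L, max_interval = 10L,
                            small_interval_bias = 0.35, id = NULL) {
  tessitura <- match.arg(tessitura)
  rng <- tessitura_range(tessitura)
  stopifnot(n_notes >= 1L, max_interval >= 0L,
            small_interval_bias > 0, small_interval_bias <= 1)
  pitches <- with_seed(rng_seed, {
    p <- integer(n_notes)
    p[1] <- sample(seq(rng[1], rng[2]), 1L)
    if (n_notes > 1L) {
      # truncated geometric over interval magnitudes 0..max_interval
      mags <- 0:max_interval
      w <- (1 - small_interval_bias)^mags
      for (k in 2:n_notes) {
        repeat {
          m <- sample(mags, 1L, prob = w)
          s <- sample(c(-1L, 1L), 1L)
          cand <- p[k - 1] + s * m
          if (cand >= rng[1] && cand <= rng[2]) {
            p[k] <- cand
            break
          }
        }
      }
    }
    p
  })
  structure(
    list(pitches = pitches, tessitura = tessitura,
         id = id %||% sprintf("mel_%s_%d", tessitura, rng_seed)),
    class = "melody"
  )
}

#' @export
print.melody <- function(x, ...) {
  cat(sprintf("<melody %s> tessitura=%s pitches(semitones re C4): %s\n",
              x$id, x$tessitura, paste(x$pitches, collapse = " ")))
  invisible(x)
}

#' Transpose a female-tessitura melody to the male tessitura
#'
#' Shifts every pitch down 7 semitones (G3..G4 -> C3..C4); melodic intervals
#' are unchanged.
#'
#' @param m a `melody` with `tessitura == "female"`.
#' @return the transposed `melody`.
#' @export
transpose_to_male <- function(m) {
  stopifnot(inherits(m, "melody"))
  if (m$tessitura != "female")
    stop("transpose_to_male() expects a female-tessitura melody")
  structure(
    list(pitches = m$pitches - 7L, tessitura = "male",
         id = paste0(m$id, "_male")),
    class = "melody"
  )
}

#' Frequencies (Hz) of a melody's notes
#' @param m a `melody`.
#' @return numeric vector of fundamental frequencies.
#' @export
melody_freqs <- function(m) semitone_to_hz(m$pitches)

#' Target intervals of a melody in cents
#' @param m a `melody`.
#' @return numeric vector of length `length(pitches) - 1` (semitones * 100).
#' @export
melody_intervals_cents <- function(m) diff(m$pitches) * 100
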