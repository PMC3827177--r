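test_that("cents is antisymmetric with known values", {
  expect_equal(cents(220, 440), 1200)
  expect_equal(cents(440, 440), 0)
  expect_equal(cents(196.00, 207.65), 100, tolerance = 1e-3)
  expect_equal(cents(300, 200), -cents(200, 300))
  expect_error(cents(0, 220), "positive")
  expect_error(cents(220, -1), "positive")
})

test_that("pitch tracker resolves a pure tone within 1 cent", {
  sr <- 44100
  t <- (0:(sr - 1)) / sr
  clip <- erdvoice:::new_audio_clip(
    sin(2 * pi * 220 * t), sr,
    data.frame(note_index = 1, start_s = 0, end_s = 1,
               target_semitone = NA))
  med <- note_median_f0(estimate_f0(clip))
  expect_lt(abs(1200 * log2(med / 220)), 1)
})

test_that("silence is unvoiced and short audio errors", {
  sr <- 44100
  clip <- erdvoice:::new_audio_clip(numeric(sr), sr, NULL)
  tr <- estimate_f0(clip)
  expect_true(all(!tr$frames$voiced))
  short <- erdvoice:::new_audio_clip(numeric(100), sr, NULL)
  expect_error(estimate_f0(short), "frame")
})

test_that("G3 triangle note tracks at 196 Hz within 1 cent", {
  g3 <- structure(list(pitches = -5L, tessitura = "female", id = "g3"),
                  class = "melody")
  med <- note_median_f0(estimate_f0(synth_triangle(g3)))
  expect_lt(abs(1200 * log2(med / 196.00)), 1)
})

test_that("perfect rendition scores zero and is transposition-invariant", {
  m <- generate_melody(2, "female")
  exact <- f0_track_from_notes(melody_freqs(m))
  s <- score_accuracy(exact, m)
  expect_equal(s$mean_abs_dev, 0)
  expect_false(s$excluded)
  # every note shifted by the same 30 cents: intervals unchanged
  shifted <- f0_track_from_notes(melody_freqs(m) * 2^(30 / 1200))
  expect_equal(score_accuracy(shifted, m)$deviations, rep(0, 4))
  # tracked (not constructed) perfect rendition stays under 2 cents
  tracked <- estimate_f0(synth_triangle(m))
  expect_lt(score_accuracy(tracked, m)$mean_abs_dev, 2)
})

test_that("one note off by +50 cents deviates two intervals by 50", {
  m <- generate_melody(2, "female")
  f <- melody_freqs(m)
  f[3] <- f[3] * 2^(50 / 1200)
  s <- score_accuracy(f0_track_from_notes(f), m)
  expect_equal(s$deviations, c(0, 50, 50, 0), tolerance = 1e-9)
  expect_equal(s$mean_abs_dev, 25, tolerance = 1e-9)
})

test_that("renditions with missing notes are excluded", {
  m <- generate_melody(2, "female")
  four <- f0_track_from_notes(melody_freqs(m)[1:4])
  s <- score_accuracy(four, m)
  expect_true(s$excluded)
  expect_true(is.na(s$mean_abs_dev))
})

test_that("alternating periods give the closed-form jitter", {
  # cycles of 200 and 202 samples: jitter = 2 / 201 = 0.995%
  periods <- rep(c(200L, 202L), 30)
  x <- unlist(lapply(periods, function(p) sin(2 * pi * (0:(p - 1)) / p)))
  sr <- 40000
  clip <- erdvoice:::new_audio_clip(
    x, sr, data.frame(note_index = 1, start_s = 0,
                      end_s = length(x) / sr, target_semitone = NA))
  js <- jitter_shimmer(clip)
  expect_equal(js$jitter_pct, 100 * 2 / 201, tolerance = 1e-3)
  expect_lt(js$shimmer_pct, 0.05)   # constant amplitude
})

test_that("fewer than three cycles is an error", {
  sr <- 44100
  x <- sin(2 * pi * 100 * (0:(round(0.025 * sr))) / sr)
  clip <- erdvoice:::new_audio_clip(
    x, sr, data.frame(note_index = 1, start_s = 0, end_s = 0.025,
                      target_semitone = NA))
  expect_error(jitter_shimmer(clip, edge_trim_s = 0), "cycles")
})

test_that("jitter and shimmer are scale-invariant", {
  m <- generate_melody(9, "female")
  clip <- synth_vocal_like(m, rng_seed = 3)
  half <- clip; half$samples <- half$samples * 0.5
  expect_equal(jitter_shimmer(clip), jitter_shimmer(half))
})

test_that("session bookkeeping counts 4 intervals per melody", {
  m <- lapply(1:10, generate_melody, tessitura = "female")
  scores <- lapply(m, function(mm)
    score_accuracy(f0_track_from_notes(melody_freqs(mm)), mm))
  agg <- aggregate_accuracy(scores)
  expect_identical(agg$n_intervals, 40L)
  expect_identical(agg$n_excluded, 0L)
})

test_that("sung-response generator matches its configured inaccuracy", {
  prof <- list(vocal_inaccuracy_cents = 52, id = "P01")
  m <- lapply(1:120, generate_melody, tessitura = "female")
  scores <- lapply(seq_along(m), function(i)
    score_accuracy(simulate_sung_response(prof, m[[i]], rng_seed = i),
                   m[[i]]))
  agg <- aggregate_accuracy(scores)
  expect_gte(agg$mean_abs_dev_cents, 42)
  expect_lte(agg$mean_abs_dev_cents, 62)
  # zero-error limit and determinism
  prof0 <- list(vocal_inaccuracy_cents = 0)
  s0 <- score_accuracy(simulate_sung_response(prof0, m[[1]], rng_seed = 1),
                       m[[1]])
  expect_lt(s0$mean_abs_dev, 2)
  expect_identical(simulate_sung_response(prof, m[[1]], rng_seed = 9),
                   simulate_sung_response(prof, m[[1]], rng_seed = 9))
})
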