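# synthetic beat/record generator and noise model

test_that("generate_beat has the right length and peak amplitude", {
  p <- beat_params()
  b <- generate_beat(p, fs = 250, rr = 1.0)
  expect_length(b, 250)
  expect_lt(abs(max(b) - p$amplitudes[["R"]]) / p$amplitudes[["R"]], 0.01)
  expect_error(generate_beat(p, fs = 250, rr = 0.3), "rr")
  expect_error(generate_beat(p, fs = 250, rr = 2.5), "rr")
  expect_error(generate_beat(p, fs = 80, rr = 1), "fs")
})

test_that("st_offset raises the ST window mean by the requested amount", {
  fs <- 1000  # fine grid so the window mean is well resolved
  p0 <- beat_params(st_offset = 0)
  p1 <- beat_params(st_offset = 0.2)
  b0 <- generate_beat(p0, fs, 1.0)
  b1 <- generate_beat(p1, fs, 1.0)
  # interior of the ST window (inset past the gate ramps), relative to R at
  # 0.24 * rr + 0.12 s into the beat
  r_at <- 0.24 * 1.0 + 0.12
  lo <- round((r_at + 0.045 + 0.04 + 0.012) * fs)
  hi <- round((r_at + 0.28 - 0.05 - 0.012) * fs)
  d <- mean(b1[lo:hi]) - mean(b0[lo:hi])
  expect_lt(abs(d - 0.2) / 0.2, 0.01)
})

test_that("beat parameter invariants are enforced", {
  expect_error(beat_params(widths = c(P = 0.02, Q = -0.01, R = 0.01,
                                      S = 0.01, T = 0.05)), "widths")
  expect_error(beat_params(centers = c(P = 0.1, Q = -0.045, R = 0,
                                       S = 0.045, T = 0.28)), "ordered")
  expect_error(beat_params(amplitudes = c(P = 0.1, Q = -0.1, R = -1,
                                          S = -0.2, T = 0.3)), "R amplitude")
})

test_that("generate_record yields the requested length and beat count", {
  rec <- generate_record("normal", minutes = 2, n_leads = 2, fs = 250,
                         hr_mean = 60, seed = 1)
  expect_identical(dim(rec$signals), c(2L, 30000L))
  expect_identical(rec$label, "normal")
  n_peaks <- count_r_peaks(rec$signals[1, ], 250)
  expect_gte(n_peaks, 114)  # ~120 beats at 60 bpm with 3% RR jitter
  expect_lte(n_peaks, 126)
})

test_that("generator is deterministic under a fixed seed", {
  a <- generate_record("ischemia_st_elev", minutes = 1, seed = 99)
  b <- generate_record("ischemia_st_elev", minutes = 1, seed = 99)
  expect_identical(a$signals, b$signals)
  na <- add_noise(a, noise_params(), seed = 5)
  nb <- add_noise(b, noise_params(), seed = 5)
  expect_identical(na$signals, nb$signals)
  expect_false(identical(
    generate_record("normal", minutes = 1, seed = 1)$signals,
    generate_record("normal", minutes = 1, seed = 2)$signals))
})

test_that("condition presets map to labels and morphology", {
  expect_identical(generate_record("ischemia_st_dep", 1, seed = 1)$label,
                   "ischemia")
  expect_identical(generate_record("infarction", 1, seed = 1)$label,
                   "infarction")
  expect_error(generate_record("arrhythmia", 1, seed = 1))
  # infarction preset inverts the T wave
  expect_lt(condition_params("infarction")$amplitudes[["T"]], 0)
})

test_that("a 120-minute record at 250 Hz has 1.8 million samples per lead", {
  rec <- generate_record("normal", minutes = 120, n_leads = 1, fs = 250,
                         hr_mean = 70, seed = 3)
  expect_identical(ncol(rec$signals), 1800000L)
})

test_that("zero noise is the identity; components land at their frequencies", {
  rec <- generate_record("normal", minutes = 1, n_leads = 1, seed = 11)
  expect_identical(add_noise(rec, noise_params(0, 0.25, 0, 0), 1)$signals,
                   rec$signals)

  noisy <- add_noise(rec, noise_params(baseline_amp = 0.5,
                                       baseline_freq = 0.25,
                                       mains_amp = 0, muscle_sd = 0), 1)
  d <- noisy$signals[1, ] - rec$signals[1, ]
  expect_lt(abs(fft_peak_freq(d, 250) - 0.25), 0.02)

  noisy <- add_noise(rec, noise_params(0, 0.25, mains_amp = 0.05,
                                       muscle_sd = 0), 1)
  d <- noisy$signals[1, ] - rec$signals[1, ]
  expect_lt(abs(fft_peak_freq(d, 250) - 50), 0.2)
})
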