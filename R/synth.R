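# Synthetic multi-lead ECG generation -----------------------------------------
#
# The generator emulates the structure of the clinical recordings the
# detection scheme targets: long multi-lead records (1-7 leads, tens of
# minutes, 128/133/250 Hz) of repeated P-QRS-T complexes, with controllable
# ST-segment and PR-segment level shifts, plus the three noise classes the
# pre-processing stage is designed to remove (baseline wander, 50 Hz mains,
# broadband muscle activity).  Beats are sums of five Gaussian waves with
# explicit piecewise-constant ST/PR pedestals, which gives direct, auditable
# control over exactly the quantities the spectral features measure.

#' Beat morphology parameters
#'
#' One Gaussian per wave (P, Q, R, S, T): amplitude in mV, centre offset in
#' seconds relative to the R peak, width (Gaussian sd) in seconds; plus
#' piecewise-constant level shifts for the ST segment (between S end and T
#' start) and the PR segment (between P end and Q start).
#'
#' Default amplitudes and timings follow textbook adult sinus morphology.
#'
#' @param amplitudes named numeric vector, mV.
#' @param centers named numeric vector, s relative to the R peak (ordered
#'   P < Q < R < S < T; R at 0).
#' @param widths named numeric vector of Gaussian sds, s (> 0).
#' @param st_offset ST-segment level shift in mV (ischemic elevation > 0,
#'   depression < 0).
#' @param pr_offset PR-segment level shift in mV.
#' @return a `beat_params` list.
#' @export
beat_params <- function(
    amplitudes = c(P = 0.12, Q = -0.10, R = 1.10, S = -0.22, T = 0.30),
    centers    = c(P = -0.18, Q = -0.045, R = 0, S = 0.045, T = 0.28),
    widths     = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.050),
    st_offset = 0, pr_offset = 0) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(amplitudes), waves),
            setequal(names(centers), waves),
            setequal(names(widths), waves))
  amplitudes <- amplitudes[waves]; centers <- centers[waves]
  widths <- widths[waves]
  if (any(widths <= 0)) stop("wave widths must be > 0")
  if (amplitudes[["R"]] <= 0) stop("R amplitude must be > 0")
  if (is.unsorted(centers, strictly = TRUE))
    stop("wave centres must be strictly ordered P < Q < R < S < T")
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths,
                 st_offset = st_offset, pr_offset = pr_offset),
            class = "beat_params")
}

# fiducial windows for the level pedestals, s relative to the R peak
st_window <- function(p) c(p$centers[["S"]] + 0.04, p$centers[["T"]] - 0.05)
pr_window <- function(p) c(p$centers[["P"]] + 0.03, p$centers[["Q"]] - 0.02)

# smooth 0/1 gate over [a, b] with ~8 ms cosine ramps, so the pedestal does
# not inject broadband step energy
soft_gate <- function(t, a, b, ramp = 0.008) {
  up <- stats::plogis((t - a) / (ramp / 4))
  dn <- stats::plogis((b - t) / (ramp / 4))
  up * dn
}

#' Generate one synthetic heart beat
#'
#' Samples one RR interval of the five-Gaussian beat model.  The R peak is
#' placed `0.24 * rr + 0.12` s into the interval so the P wave fits and the
#' complex scales gently with rate.
#'
#' @param params a [beat_params()].
#' @param fs sampling rate in Hz (>= 100).
#' @param rr RR interval in seconds, in `[0.4, 2]`.
#' @return numeric vector of `round(rr * fs)` samples (mV).
#' @export
generate_beat <- function(params, fs, rr) {
  stopifnot(inherits(params, "beat_params"))
  if (fs < 100) stop("`fs` must be >= 100 Hz")
  if (rr < 0.4 || rr > 2.0) stop("`rr` must lie in [0.4, 2.0] s")
  n <- round(rr * fs)
  t <- (seq_len(n) - 1) / fs - (0.24 * rr + 0.12)  # 0 at the R peak
  y <- numeric(n)
  for (w in c("P", "Q", "R", "S", "T")) {
    y <- y + params$amplitudes[[w]] *
      exp(-(t - params$centers[[w]])^2 / (2 * params$widths[[w]]^2))
  }
  if (params$st_offset != 0) {
    win <- st_window(params)
    y <- y + params$st_offset * soft_gate(t, win[1], win[2])
  }
  if (params$pr_offset != 0) {
    win <- pr_window(params)
    y <- y + params$pr_offset * soft_gate(t, win[1], win[2])
  }
  y
}

#' Condition presets for the generator
#'
#' Maps a condition name to beat parameters: `ischemia_st_elev` raises the
#' ST pedestal by +0.15 mV, `ischemia_st_dep` lowers it by 0.15 mV, and
#' `infarction` combines a +0.30 mV ST elevation with T-wave inversion.
#' These magnitudes are generator conventions in the clinically meaningful
#' range (0.1-0.3 mV), not measurements of any particular dataset.
#'
#' @param condition one of `"normal"`, `"ischemia_st_elev"`,
#'   `"ischemia_st_dep"`, `"infarction"`.
#' @return a [beat_params()].
#' @export
condition_params <- function(condition = c("normal", "ischemia_st_elev",
                                           "ischemia_st_dep", "infarction")) {
  condition <- match.arg(condition)
  switch(condition,
    normal = beat_params(),
    ischemia_st_elev = beat_params(st_offset = 0.15),
    ischemia_st_dep = beat_params(st_offset = -0.15),
    infarction = {
      p <- beat_params(st_offset = 0.30)
      p$amplitudes[["T"]] <- -abs(p$amplitudes[["T"]])
      p
    })
}

condition_label <- function(condition) {
  switch(condition,
         normal = "normal",
         ischemia_st_elev = "ischemia",
         ischemia_st_dep = "ischemia",
         infarction = "infarction")
}

#' Generate a labelled synthetic multi-lead ECG record
#'
#' Concatenates beats from the condition's preset morphology with Gaussian
#' RR jitter (sd 3% of the mean RR, truncated at +/-10%), and scales each
#' lead by a random gain in `[0.7, 1.3]` to mimic inter-lead amplitude
#' diversity.  Deterministic for a fixed seed.
#'
#' @inheritParams condition_params
#' @param minutes record length in whole minutes (>= 1).
#' @param n_leads number of leads (1-12).
#' @param fs sampling rate in Hz.
#' @param hr_mean mean heart rate in beats per minute.
#' @param seed integer RNG seed.
#' @return an [ecg_record()] with exactly `minutes * 60 * fs` samples per
#'   lead and the condition's class label.
#' @export
generate_record <- function(condition = "normal", minutes = 2, n_leads = 2,
                            fs = 250, hr_mean = 70, seed = 1) {
  condition <- match.arg(condition, c("normal", "ischemia_st_elev",
                                      "ischemia_st_dep", "infarction"))
  if (minutes < 1) stop("`minutes` must be >= 1")
  if (n_leads < 1 || n_leads > 12) stop("`n_leads` must lie in 1..12")
  params <- condition_params(condition)
  n_total <- as.integer(round(minutes * 60 * fs))
  rr_mean <- 60 / hr_mean

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))

  base <- numeric(n_total + as.integer(2 * fs))
  filled <- 0L
  while (filled < n_total) {
    rr <- rr_mean * (1 + max(-0.1, min(0.1, stats::rnorm(1, 0, 0.03))))
    beat <- generate_beat(params, fs, rr)
    take <- min(length(beat), length(base) - filled)
    base[filled + seq_len(take)] <- beat[seq_len(take)]
    filled <- filled + take
  }
  base <- base[seq_len(n_total)]

  gains <- stats::runif(n_leads, 0.7, 1.3)
  sig <- matrix(0, nrow = n_leads, ncol = n_total)
  for (l in seq_len(n_leads)) sig[l, ] <- gains[l] * base

  ecg_record(sig, fs = fs,
             lead_names = c("I", "II", "III", "V1", "V2", "V3", "V4", "V5",
                            "V6", "aVR", "aVL", "aVF")[seq_len(n_leads)],
             label = condition_label(condition),
             record_id = sprintf("synth_%s_%d", condition, seed))
}

#' Noise model parameters
#'
#' Additive noise components: a baseline-wander sinusoid (respiratory-rate
#' drift, default 0.25 Hz), 50 Hz mains interference, and band-limited
#' (20-100 Hz) Gaussian muscle noise.
#'
#' @param baseline_amp baseline wander amplitude, mV.
#' @param baseline_freq baseline wander frequency, Hz.
#' @param mains_amp 50 Hz mains amplitude, mV.
#' @param muscle_sd muscle-noise standard deviation, mV.
#' @return a `noise_params` list.
#' @export
noise_params <- function(baseline_amp = 0.10, baseline_freq = 0.25,
                         mains_amp = 0.02, muscle_sd = 0.03) {
  if (baseline_amp < 0 || mains_amp < 0 || muscle_sd < 0 || baseline_freq < 0)
    stop("noise amplitudes and frequencies must be >= 0")
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 mains_amp = mains_amp, muscle_sd = muscle_sd),
            class = "noise_params")
}

#' Add synthetic noise to an ECG record
#'
#' Adds, per lead: `baseline_amp * sin(2 pi baseline_freq t + phase)`,
#' `mains_amp * sin(2 pi 50 t + phase)` (phases drawn per lead), and
#' white Gaussian noise band-passed to 20-100 Hz (upper edge capped at
#' `0.45 * fs` for low sampling rates).  Deterministic under the seed.
#'
#' @param record an [ecg_record()].
#' @param noise a [noise_params()].
#' @param seed integer RNG seed.
#' @return the noisy [ecg_record()].
#' @export
add_noise <- function(record, noise = noise_params(), seed = 1) {
  stopifnot(inherits(record, "ecg_record"), inherits(noise, "noise_params"))
  if (noise$baseline_amp == 0 && noise$mains_amp == 0 && noise$muscle_sd == 0)
    return(record)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))

  n <- n_samples(record); fs <- record$fs
  t <- (seq_len(n) - 1) / fs
  sig <- record$signals
  hi <- min(100, 0.45 * fs)
  bp <- if (noise$muscle_sd > 0)
    signal::fir1(200, c(20, hi) / (fs / 2), type = "pass") else NULL
  for (l in seq_len(nrow(sig))) {
    add <- numeric(n)
    if (noise$baseline_amp > 0)
      add <- add + noise$baseline_amp *
        sin(2 * pi * noise$baseline_freq * t + stats::runif(1, 0, 2 * pi))
    if (noise$mains_amp > 0)
      add <- add + noise$mains_amp *
        sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    if (noise$muscle_sd > 0) {
      w <- stats::rnorm(n)
      w <- fir_filter_zerophase(w, bp)
      add <- add + noise$muscle_sd * w / stats::sd(w)
    }
    sig[l, ] <- sig[l, ] + add
  }
  with_signals(record, sig)
}

# save/restore the global RNG state so generator calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
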