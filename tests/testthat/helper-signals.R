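# small signal builders shared across test files

tone <- function(freq, fs = 250, dur = 2, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs + phase)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# dominant frequency of a real signal by periodogram (independent FFT oracle)
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2)]
  ((which.max(p) - 1) / n) * fs
}

# RMS of the central portion of a signal (steady-state, away from filter edges)
central_rms <- function(x, frac = 0.5) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2) + 1
  sqrt(mean(x[lo:(lo + floor(n * frac) - 1)]^2))
}

rel_frob <- function(a, b) norm(a - b, "F") / norm(b, "F")

# pooled-sd standardized mean difference
smd <- function(a, b) (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)

with_gain <- function(rec, g) {
  rec$signals <- rec$signals * g
  rec
}

# simple threshold-based R-peak counter (oracle for the generator)
count_r_peaks <- function(x, fs, thresh_frac = 0.5) {
  th <- thresh_frac * max(x)
  above <- x > th
  # rising edges of the above-threshold mask, debounced by 200 ms
  edges <- which(diff(c(FALSE, above)) == 1)
  if (length(edges) < 2) return(length(edges))
  sum(c(TRUE, diff(edges) > 0.2 * fs))
}
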