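# Choi-Williams time-frequency distribution ----------------------------------
#
# The discrete Choi-Williams distribution (CWD) of a signal x(n) is the
# Cohen's-class bilinear distribution obtained by smoothing the instantaneous
# autocorrelation x(m + k) x*(m - k) over m with a Gaussian whose width grows
# with the lag |k|, then Fourier-transforming over the lag:
#
#   CWD(n, w) = 2 sum_k e^{-i 2 w k} sum_m g_sigma(m - n; k) x(m+k) x*(m-k)
#
# with g_sigma(m; k) proportional to exp(-sigma m^2 / (4 k^2)).  The kernel
# parameter sigma trades time-frequency resolution against suppression of the
# oscillatory cross-terms that bilinear distributions place between genuine
# components.  As sigma grows the distribution approaches the (pseudo)
# Wigner-Ville distribution; small sigma smooths cross-terms away.
#
# Discretisation conventions used here (shared by cwd() and cwd_reference()):
#   * the signal is converted to its analytic form first, so all energy lives
#     in [0, fs/2) and the e^{-i 2 w k} lag sampling is alias-free;
#   * the k = 0 smoothing window is a Kronecker delta (the Gaussian's limit);
#   * for k != 0 the Gaussian is truncated at +/- ceil(4 |k| / sqrt(sigma))
#     samples (where it has fallen below ~3e-7 of its peak) and renormalised
#     to unit sum, so that the time marginal is exact;
#   * lags are tapered by a Hamming window of length lag_window (odd);
#   * the overall scale 2/fs is chosen so that the Riemann-sum marginals
#     reproduce instantaneous power, the energy spectrum shape, and total
#     signal energy (see marginal_time, marginal_freq, total_power).

#' Construct a CWD matrix object
#'
#' Internal constructor; users obtain `cwd_matrix` objects from [cwd()] or
#' [cwd_reference()].
#'
#' @param values numeric matrix, time slices in rows, frequency bins in columns.
#' @param time_axis analysed time instants in seconds.
#' @param freq_axis frequency bin centres in Hz, uniform on `[0, fs/2)`.
#' @param fs sampling rate in Hz.
#' @param sigma Choi-Williams kernel parameter.
#' @param lag_window lag window length (odd number of samples).
#' @param time_decimation stride between analysed time instants, in samples.
#' @param truncated logical; `TRUE` after [truncate_positive()].
#' @param edge_samples number of samples at each end of the segment whose
#'   slices are affected by window shrinkage.
#' @return an object of class `cwd_matrix`.
#' @keywords internal
new_cwd_matrix <- function(values, time_axis, freq_axis, fs, sigma,
                           lag_window, time_decimation,
                           truncated = FALSE, edge_samples = 0L) {
  stopifnot(is.matrix(values), nrow(values) == length(time_axis),
            ncol(values) == length(freq_axis))
  structure(
    list(values = values, time_axis = time_axis, freq_axis = freq_axis,
         fs = fs, sigma = sigma, lag_window = as.integer(lag_window),
         time_decimation = as.integer(time_decimation),
         truncated = isTRUE(truncated),
         edge_samples = as.integer(edge_samples)),
    class = "cwd_matrix")
}

#' @export
print.cwd_matrix <- function(x, ...) {
  cat(sprintf(
    "<cwd_matrix> %d time slices x %d frequency bins\n", nrow(x$values),
    ncol(x$values)))
  cat(sprintf("  fs = %g Hz, sigma = %g, lag window = %d, decimation = %d\n",
              x$fs, x$sigma, x$lag_window, x$time_decimation))
  cat(sprintf("  freq range [0, %.2f] Hz, duration %.2f s, truncated: %s\n",
              max(x$freq_axis), diff(range(x$time_axis)),
              if (x$truncated) "yes" else "no"))
  invisible(x)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Zeroes the negative-frequency half of the spectrum and doubles the positive
#' half, the standard discrete construction of the analytic signal.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Gaussian lag-dependent smoothing window, truncated and unit-normalised.
# Returns the half-window g(0..h); full window is symmetric.
cw_gauss_half <- function(k, sigma) {
  h <- as.integer(ceiling(4 * abs(k) / sqrt(sigma)))
  m <- 0:h
  g <- exp(-sigma * m^2 / (4 * k^2))
  g / (g[1] + 2 * sum(g[-1]))
}

# Hamming lag taper of odd length L, exactly 1 at the central lag.
cw_lag_taper <- function(L) {
  j <- seq_len(L) - 1
  0.54 - 0.46 * cos(2 * pi * j / (L - 1))
}

# cache of FFTs of the Gaussian smoothing windows, keyed by
# (conv length, sigma, K); avoids re-transforming them for every segment
.cwd_cache <- new.env(parent = emptyenv())

cwd_check_args <- function(signal, sigma, n_freq, lag_window) {
  if (!is.numeric(signal)) stop("`signal` must be a numeric vector")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (lag_window < 3 || lag_window %% 2 == 0)
    stop("`lag_window` must be an odd integer >= 3")
  if (length(signal) < 2 * lag_window)
    stop("signal shorter than twice the lag window (",
         length(signal), " < ", 2 * lag_window, " samples)")
  if (n_freq < lag_window)
    stop("`n_freq` must be at least `lag_window`")
}

#' Discrete Choi-Williams distribution of a signal
#'
#' Computes the discrete Choi-Williams time-frequency distribution of a real
#' signal.  The signal is converted to its analytic form, the lag-dependent
#' Gaussian smoothing of the instantaneous autocorrelation is evaluated by
#' FFT convolution per lag, and the lag axis is Fourier-transformed to
#' `n_freq` uniform frequency bins on `[0, fs/2)`.
#'
#' The normalisation is fixed so that, before positive-part truncation,
#' the distribution's Riemann-sum marginals recover instantaneous power
#' ([marginal_time()]), the energy-spectrum shape ([marginal_freq()]) and the
#' analytic signal's total energy ([total_power()]).
#'
#' @param signal real numeric vector (mV or any consistent unit).
#' @param fs sampling rate in Hz.
#' @param sigma Choi-Williams kernel parameter (> 0).  Smaller values
#'   suppress cross-terms more aggressively at the cost of resolution.
#' @param n_freq number of frequency bins on `[0, fs/2)`; a power of two
#'   keeps the lag FFTs fast.
#' @param lag_window odd lag-window length in samples; lags are tapered by a
#'   Hamming window.
#' @param time_decimation stride between analysed time instants in samples;
#'   1 analyses every sample.
#' @return a [new_cwd_matrix()] object, `time x frequency`, real-valued.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 250))
#' m <- cwd(x, fs = 250, sigma = 1, n_freq = 128, lag_window = 63)
#' m$freq_axis[which.max(colMeans(m$values))]  # ~10 Hz
#' @export
cwd <- function(signal, fs, sigma = 1, n_freq = 256L, lag_window = 127L,
                time_decimation = 4L) {
  cwd_check_args(signal, sigma, n_freq, lag_window)
  if (time_decimation < 1) stop("`time_decimation` must be >= 1")
  n_freq <- as.integer(n_freq)
  N <- length(signal)
  x <- analytic_signal(signal)
  K <- (lag_window - 1L) %/% 2L
  taper <- cw_lag_taper(lag_window)
  w <- taper[(K + 1L):lag_window]          # w[k+1] = taper at lag +k

  idx <- seq(1L, N, by = as.integer(time_decimation))
  nt <- length(idx)

  # maximal Gaussian half-width fixes one FFT length for all lags
  hmax <- as.integer(ceiling(4 * K / sqrt(sigma)))
  nfft <- stats::nextn(N + 2L * hmax, 2)
  key <- paste(nfft, sigma, K, sep = "_")
  if (is.null(.cwd_cache[[key]])) {
    Gf <- vector("list", K)
    for (k in seq_len(K)) {
      gh <- cw_gauss_half(k, sigma)
      h <- length(gh) - 1L
      g <- numeric(nfft)
      g[1] <- gh[1]
      if (h > 0) {
        g[2:(h + 1)] <- gh[-1]                       # m = +1..+h
        g[(nfft - h + 1):nfft] <- rev(gh[-1])        # m = -h..-1 (wrapped)
      }
      Gf[[k]] <- stats::fft(g)
    }
    .cwd_cache[[key]] <- Gf
  }
  Gf <- .cwd_cache[[key]]

  # accumulate the lag slices of the FFT input: A[lag bin, time slice]
  A <- matrix(0 + 0i, nrow = n_freq, ncol = nt)
  A[1L, ] <- w[1L] * abs(x[idx])^2                    # k = 0: delta window
  pk <- complex(length.out = nfft)
  for (k in seq_len(K)) {
    pk[] <- 0 + 0i
    m <- (k + 1L):(N - k)                             # valid centres
    pk[m] <- x[m + k] * Conj(x[m - k])
    Rk <- stats::fft(stats::fft(pk) * Gf[[k]], inverse = TRUE)[seq_len(N)] /
      nfft
    Rk <- w[k + 1L] * Rk[idx]
    A[k + 1L, ] <- Rk
    A[n_freq - k + 1L, ] <- Conj(Rk)
  }

  vals <- t(Re(stats::mvfft(A))) * (2 / fs)
  new_cwd_matrix(
    values = vals,
    time_axis = (idx - 1L) / fs,
    freq_axis = (0:(n_freq - 1L)) * fs / (2 * n_freq),
    fs = fs, sigma = sigma, lag_window = lag_window,
    time_decimation = time_decimation,
    edge_samples = lag_window)
}

#' Naive reference evaluation of the discrete Choi-Williams distribution
#'
#' Literal nested-loop transcription of the discrete CWD double sum, under
#' the same discretisation conventions as [cwd()] (analytic signal, delta
#' window at lag zero, truncated unit-sum Gaussian smoothing, Hamming lag
#' taper, `2/fs` scale).  It shares no computational machinery with the FFT
#' path of [cwd()] and exists as an independent cross-check for small inputs.
#'
#' @inheritParams cwd
#' @return a [new_cwd_matrix()] object.
#' @export
cwd_reference <- function(signal, fs, sigma = 1, n_freq = 64L,
                          lag_window = 31L, time_decimation = 1L) {
  if (length(signal) > 256)
    stop("cwd_reference() is a small-instance oracle; length(signal) must be <= 256")
  cwd_check_args(signal, sigma, n_freq, lag_window)
  n_freq <- as.integer(n_freq)
  N <- length(signal)
  x <- analytic_signal(signal)
  K <- (lag_window - 1L) %/% 2L
  taper <- cw_lag_taper(lag_window)

  idx <- seq(1L, N, by = as.integer(time_decimation))
  vals <- matrix(0, nrow = length(idx), ncol = n_freq)
  jfreq <- 0:(n_freq - 1L)

  for (ti in seq_along(idx)) {
    n <- idx[ti]
    acc <- rep(0 + 0i, n_freq)
    acc <- acc + taper[K + 1L] * abs(x[n])^2          # k = 0 term
    for (k in seq_len(K)) {
      gh <- cw_gauss_half(k, sigma)
      h <- length(gh) - 1L
      Rnk <- 0 + 0i
      for (m in (n - h):(n + h)) {
        if (m - k >= 1 && m + k <= N) {
          Rnk <- Rnk + gh[abs(m - n) + 1L] * x[m + k] * Conj(x[m - k])
        }
      }
      Rnk <- taper[K + 1L + k] * Rnk
      ph <- exp(-2i * pi * jfreq * k / n_freq)
      acc <- acc + Rnk * ph + Conj(Rnk) * Conj(ph)
    }
    vals[ti, ] <- Re(acc) * (2 / fs)
  }

  new_cwd_matrix(
    values = vals,
    time_axis = (idx - 1L) / fs,
    freq_axis = (0:(n_freq - 1L)) * fs / (2 * n_freq),
    fs = fs, sigma = sigma, lag_window = lag_window,
    time_decimation = time_decimation,
    edge_samples = lag_window)
}

#' Positive-part truncation of a Choi-Williams matrix
#'
#' Zeroes every non-positive element of the distribution, on the premise that
#' the signal information of a Cohen's-class matrix resides in its positive
#' part while the negative part belongs to the oscillatory cross-terms.
#'
#' @param m a `cwd_matrix` that has not yet been truncated.
#' @return the truncated `cwd_matrix` (`truncated = TRUE`, all values >= 0).
#' @export
truncate_positive <- function(m) {
  stopifnot(inherits(m, "cwd_matrix"))
  if (m$truncated) stop("matrix is already truncated")
  m$values <- pmax(m$values, 0)
  m$truncated <- TRUE
  m
}

check_untruncated <- function(m, what) {
  stopifnot(inherits(m, "cwd_matrix"))
  if (m$truncated)
    stop(what, " is defined for the full (untruncated) distribution; ",
         "got a positive-part truncated matrix")
}

#' Time marginal (instantaneous power) of a CWD matrix
#'
#' Riemann sum over frequency.  For the full (untruncated) distribution this
#' recovers the analytic signal's instantaneous power `|s(t)|^2` at each
#' analysed instant.
#'
#' @param m an untruncated `cwd_matrix`.
#' @return numeric vector over the analysed time instants.
#' @export
marginal_time <- function(m) {
  check_untruncated(m, "the time marginal")
  df <- m$fs / (2 * ncol(m$values))
  rowSums(m$values) * df
}

#' Frequency marginal (energy spectrum) of a CWD matrix
#'
#' Riemann sum over time.  For the full distribution of a well-windowed
#' signal this matches the shape of the analytic signal's energy spectrum.
#'
#' @param m an untruncated `cwd_matrix`.
#' @return numeric vector over the frequency bins.
#' @export
marginal_freq <- function(m) {
  check_untruncated(m, "the frequency marginal")
  dt <- m$time_decimation / m$fs
  colSums(m$values) * dt
}

#' Total power of a CWD matrix
#'
#' Double Riemann sum over time and frequency; equals the analytic signal's
#' energy `sum |s(n)|^2 / fs` for well-windowed signals.
#'
#' @param m an untruncated `cwd_matrix`.
#' @return scalar.
#' @export
total_power <- function(m) {
  check_untruncated(m, "the total power")
  df <- m$fs / (2 * ncol(m$values))
  dt <- m$time_decimation / m$fs
  sum(m$values) * df * dt
}
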