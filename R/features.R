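# ST/PR band-power feature extraction -----------------------------------------
#
# Myocardial ischemia shifts the ST segment relative to the PR baseline, and
# these morphology changes concentrate spectrally: the ST segment in the
# 11-14 Hz band and the PR segment in the 5-8.5 Hz band.  The features are
# the mean positive-part Choi-Williams energy in those bands, normalised to
# the share (in percent) of the 0-35 Hz post-filter total, one pair per
# one-minute segment per lead.

ST_BAND <- c(11, 14)
PR_BAND <- c(5, 8.5)
FULL_BAND <- c(0, 35)

#' Mean band power of a truncated CWD matrix
#'
#' Mean of all matrix elements whose frequency-bin centre lies in the closed
#' band `[f_lo, f_hi]`, over all time slices.  Requires the positive-part
#' truncated distribution ([truncate_positive()]), since the features are
#' defined on the positive part only.
#'
#' @param m a truncated `cwd_matrix`.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return non-negative scalar.
#' @export
band_mean_power <- function(m, f_lo, f_hi) {
  stopifnot(inherits(m, "cwd_matrix"))
  if (!m$truncated)
    stop("band powers are defined on the positive-part truncated matrix; ",
         "apply truncate_positive() first")
  if (f_lo < 0 || f_hi > m$fs / 2 || f_lo >= f_hi)
    stop("band edges must satisfy 0 <= f_lo < f_hi <= fs/2")
  sel <- m$freq_axis >= f_lo & m$freq_axis <= f_hi
  if (!any(sel))
    stop("no frequency bin centre falls inside [", f_lo, ", ", f_hi, "] Hz")
  mean(m$values[, sel])
}

#' Time-frequency analysis settings
#'
#' @param sigma Choi-Williams kernel parameter.
#' @param n_freq number of frequency bins.
#' @param lag_window lag window length (odd, samples).
#' @param time_decimation time stride in samples.
#' @return a `tfd_config` list.
#' @export
tfd_config <- function(sigma = 1, n_freq = 256L, lag_window = 127L,
                       time_decimation = 4L) {
  stopifnot(sigma > 0, lag_window %% 2 == 1, time_decimation >= 1)
  structure(list(sigma = sigma, n_freq = as.integer(n_freq),
                 lag_window = as.integer(lag_window),
                 time_decimation = as.integer(time_decimation)),
            class = "tfd_config")
}

#' Extract the ST/PR feature pair from a one-minute segment
#'
#' Computes the Choi-Williams distribution of the segment, truncates to its
#' positive part, and measures the mean power in the ST (11-14 Hz) and PR
#' (5-8.5 Hz) bands.  Each band's power is normalised as a percentage of
#' the total 0-35 Hz positive power of the same segment (band total /
#' full-band total x 100), so both features lie in `[0, 100]` and sum to at
#' most 100.
#'
#' @param segment a [minute_segment()].
#' @param config a [tfd_config()].
#' @return one-row [feature_table()].
#' @export
extract_st_pr <- function(segment, config = tfd_config()) {
  stopifnot(inherits(segment, "minute_segment"),
            inherits(config, "tfd_config"))
  if (all(segment$samples == 0)) {
    warning("all-zero segment; returning (0, 0) features")
    p_st <- 0; p_pr <- 0
  } else {
    m <- cwd(segment$samples, segment$fs, sigma = config$sigma,
             n_freq = config$n_freq, lag_window = config$lag_window,
             time_decimation = config$time_decimation)
    m <- truncate_positive(m)
    nbin <- function(b) sum(m$freq_axis >= b[1] & m$freq_axis <= b[2])
    tot <- band_mean_power(m, FULL_BAND[1], FULL_BAND[2]) * nbin(FULL_BAND)
    if (tot <= 0) {
      p_st <- 0; p_pr <- 0
    } else {
      p_st <- 100 * band_mean_power(m, ST_BAND[1], ST_BAND[2]) *
        nbin(ST_BAND) / tot
      p_pr <- 100 * band_mean_power(m, PR_BAND[1], PR_BAND[2]) *
        nbin(PR_BAND) / tot
    }
  }
  feature_table(data.frame(
    record_id = segment$record_id, segment_index = segment$segment_index,
    lead_name = segment$lead_name, p_st = p_st, p_pr = p_pr,
    label = if (is.null(segment$label)) NA_character_ else segment$label))
}

#' Extract the feature table of a set of preprocessed records
#'
#' Segments each record into minutes and extracts the ST/PR pair for every
#' (record, segment, lead).  Per-segment failures are logged as warnings and
#' skipped, not fatal.
#'
#' @param records list of preprocessed [ecg_record()] objects.
#' @param config a [tfd_config()].
#' @param progress print a line per record.
#' @return a [feature_table()].
#' @export
extract_dataset <- function(records, config = tfd_config(),
                            progress = FALSE) {
  if (inherits(records, "ecg_record")) records <- list(records)
  rows <- list()
  for (rec in records) {
    if (progress)
      message("features: ", rec$record_id)
    segs <- segment_minutes(rec)
    for (sg in segs) {
      row <- tryCatch(extract_st_pr(sg, config), error = function(e) {
        warning("skipping ", rec$record_id, " segment ", sg$segment_index,
                " lead ", sg$lead_name, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  feature_table(do.call(rbind, lapply(rows, as.data.frame)))
}
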