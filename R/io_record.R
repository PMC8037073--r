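# ECG record container and file I/O ------------------------------------------

VALID_LABELS <- c("normal", "ischemia", "infarction")

#' Create a multi-lead ECG record
#'
#' The central container of the package: a leads-by-samples matrix of
#' amplitudes in millivolts, a sampling rate, and lead names.
#'
#' @param signals numeric matrix `[n_leads x n_samples]`, amplitudes in mV.
#'   A vector is taken as a single lead.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_names character vector of unique lead names (e.g. `"I"`,
#'   `"III"`, `"V1"`); defaults to `L1, L2, ...`.
#' @param label optional ground-truth class, one of
#'   `"normal"`, `"ischemia"`, `"infarction"`.
#' @param record_id identifier string.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, lead_names = NULL, label = NULL,
                       record_id = "record") {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix [n_leads x n_samples]")
  if (nrow(signals) < 1 || ncol(signals) < 1)
    stop("record must contain at least one lead and one sample")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(lead_names))
    lead_names <- paste0("L", seq_len(nrow(signals)))
  lead_names <- as.character(lead_names)
  if (length(lead_names) != nrow(signals))
    stop("length(lead_names) must equal the number of leads")
  if (anyDuplicated(lead_names))
    stop("lead names must be unique")
  if (!is.null(label)) {
    label <- match.arg(label, VALID_LABELS)
  }
  rownames(signals) <- lead_names
  structure(
    list(signals = signals, fs = fs, lead_names = lead_names,
         label = label, record_id = as.character(record_id)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s': %d lead(s) x %d samples @ %g Hz (%.1f min)\n",
              x$record_id, nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs / 60))
  cat(sprintf("  leads: %s | label: %s\n",
              paste(x$lead_names, collapse = ", "),
              if (is.null(x$label)) "<none>" else x$label))
  invisible(x)
}

n_leads <- function(record) nrow(record$signals)
n_samples <- function(record) ncol(record$signals)

# replace the sample matrix, keeping metadata
with_signals <- function(record, signals, fs = record$fs) {
  ecg_record(signals, fs, record$lead_names, record$label, record$record_id)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read an ECG record from disk
#'
#' Two on-disk layouts are supported: purely numeric CSV (one column per
#' lead, header row of lead names) with a JSON sidecar carrying the sampling
#' rate and metadata, and WFDB-style signal/header pairs (`.hea` + 16-bit
#' `.dat`, gain and baseline applied so samples come back in mV).
#'
#' @param path path to the `.csv` file or to the WFDB header/record name.
#' @param format `"csv"` or `"wfdb"`.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  switch(format,
         csv = read_record_csv(path),
         wfdb = read_record_wfdb(path))
}

#' Write an ECG record to disk
#'
#' Inverse of [read_record()]; round-trips sampling rate, lead names, label
#' and samples to the format's declared precision (CSV: full double
#' precision; WFDB: 16-bit quantisation at the stored gain).
#'
#' @param record an [ecg_record()].
#' @inheritParams read_record
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  switch(format,
         csv = write_record_csv(record, path),
         wfdb = write_record_wfdb(record, path))
  invisible(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar '", side, "' declaring the sampling rate")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar '", side, "' does not declare `fs`")
  dat <- utils::read.csv(path, check.names = FALSE)
  sig <- t(as.matrix(dat))
  ecg_record(sig, fs = as.numeric(meta$fs), lead_names = colnames(dat),
             label = if (is.null(meta$label)) NULL else meta$label,
             record_id = if (is.null(meta$record_id)) "record"
                         else meta$record_id)
}

write_record_csv <- function(record, path) {
  dat <- as.data.frame(t(record$signals))
  names(dat) <- record$lead_names
  ok <- tryCatch({
    utils::write.csv(dat, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  meta <- list(fs = record$fs, record_id = record$record_id,
               lead_names = record$lead_names)
  if (!is.null(record$label)) meta$label <- record$label
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(ok)
}

# --- minimal WFDB (format 16) support ---------------------------------------
# Interleaved little-endian 16-bit samples, one .hea header naming the .dat;
# amplitudes are (stored - baseline) / gain in mV.

WFDB_GAIN <- 2000  # ADC units per mV; 16-bit range then spans +/- 16.38 mV

read_record_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("cannot read '", hea, "': no such file")
  all_lines <- readLines(hea, warn = FALSE)
  lines <- all_lines[!grepl("^\\s*#", all_lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- top[1]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (!is.finite(fs)) stop("header '", hea, "' does not declare a sampling rate")
  sig_lines <- lines[2:(1 + nsig)]
  gains <- numeric(nsig); base <- integer(nsig); names_v <- character(nsig)
  dat_file <- NULL
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1]]
    dat_file <- f[1]
    if (f[2] != "16") stop("only WFDB format 16 is supported (got ", f[2], ")")
    gspec <- strsplit(f[3], "[(/]")[[1]][1]
    gains[i] <- as.numeric(gspec)
    bpart <- regmatches(f[3], regexpr("\\(([-0-9]+)\\)", f[3]))
    base[i] <- if (length(bpart)) as.integer(gsub("[()]", "", bpart)) else 0L
    names_v[i] <- if (length(f) >= 9) f[length(f)] else paste0("L", i)
  }
  datp <- file.path(dirname(hea), dat_file)
  raw <- readBin(datp, what = "integer", size = 2, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  if (length(raw) < nsig * nsamp)
    stop("'", datp, "' holds fewer samples than the header declares")
  m <- matrix(raw, nrow = nsig)
  sig <- (m - base) / gains
  # label comment, if we wrote one
  lab <- grep("^# label:", all_lines, value = TRUE)
  lab <- if (length(lab)) sub("^# label:\\s*", "", lab[1]) else NULL
  ecg_record(sig, fs = fs, lead_names = names_v, label = lab,
             record_id = rec_name)
}

write_record_wfdb <- function(record, path) {
  base_path <- sub("\\.hea$", "", path)
  rec_name <- basename(base_path)
  nsig <- n_leads(record); nsamp <- n_samples(record)
  q <- round(record$signals * WFDB_GAIN)
  if (any(abs(q) > 32767))
    stop("amplitudes exceed the 16-bit range at gain ", WFDB_GAIN, " adu/mV")
  con <- file(paste0(base_path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2, endian = "little")
  hdr <- c(
    sprintf("%s %d %g %d", rec_name, nsig, record$fs, nsamp),
    sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 %s", rec_name, WFDB_GAIN,
            record$lead_names))
  if (!is.null(record$label)) hdr <- c(hdr, paste0("# label: ", record$label))
  writeLines(hdr, paste0(base_path, ".hea"))
  invisible(path)
}
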