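# Feature table container and CSV round-trip ---------------------------------

#' Construct and validate a feature table
#'
#' A feature table holds one row per analysed (record, minute segment, lead)
#' with the two normalised band-power features: `p_st` (11-14 Hz share, %)
#' and `p_pr` (5-8.5 Hz share, %).
#'
#' @param df data.frame with columns `record_id`, `segment_index` (0-based),
#'   `lead_name`, `p_st`, `p_pr`, and optionally `label`.
#' @return the validated data.frame with class `feature_table`.
#' @export
feature_table <- function(df) {
  req <- c("record_id", "segment_index", "lead_name", "p_st", "p_pr")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- df[, c(req, "label")]
  df$record_id <- as.character(df$record_id)
  df$segment_index <- as.integer(df$segment_index)
  df$lead_name <- as.character(df$lead_name)
  df$label <- as.character(df$label)
  if (any(!is.finite(df$p_st)) || any(!is.finite(df$p_pr)))
    stop("p_st / p_pr must be finite")
  if (any(df$p_st < 0) || any(df$p_pr < 0))
    stop("p_st and p_pr must be non-negative (post-truncation powers)")
  key <- paste(df$record_id, df$segment_index, df$lead_name)
  if (anyDuplicated(key))
    stop("duplicate (record_id, segment_index, lead_name) rows")
  bad <- !is.na(df$label) & !(df$label %in% VALID_LABELS)
  if (any(bad))
    stop("unknown label(s): ", paste(unique(df$label[bad]), collapse = ", "))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write a feature table to CSV
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(as.data.frame(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  df <- utils::read.csv(path, colClasses = c(
    record_id = "character", lead_name = "character", label = "character"))
  df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  feature_table(df)
}
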