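# Classification-record tables.
#
# One row per image. Required columns: camera_id, timestamp (POSIXct, 1 s
# resolution), true_label (species name, "EMPTY" for blank frames, "UNKNOWN"
# for unresolvable ground truth). Optional: trigger_id. Each observer adds a
# pair <observer>_label / <observer>_confidence (confidence may be NA, as for
# human observers).

EMPTY_LABEL <- "EMPTY"
UNKNOWN_LABEL <- "UNKNOWN"

#' Observers present in a record table
#'
#' @param records a classification-record `data.frame`.
#' @return Character vector of observer names, inferred from the
#'   `<observer>_label` columns.
#' @export
observers <- function(records) {
  lab <- setdiff(grep("_label$", names(records), value = TRUE), "true_label")
  sub("_label$", "", lab)
}

label_col <- function(observer) paste0(observer, "_label")
conf_col <- function(observer) paste0(observer, "_confidence")

check_observer <- function(records, observer) {
  if (!label_col(observer) %in% names(records))
    abort("observer '%s' has no '%s' column in the records", observer,
          label_col(observer))
  invisible(observer)
}

#' Validate a classification-record table
#'
#' Checks required columns, timestamp class, label presence and confidence
#' range; error messages name the offending row and column.
#'
#' @param records a `data.frame` of per-image records.
#' @return `records` invisibly.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) abort("records must be a data.frame")
  for (col in c("camera_id", "timestamp", "true_label"))
    if (!col %in% names(records))
      abort("records are missing required column '%s'", col)
  if (!inherits(records$timestamp, "POSIXct"))
    abort("column 'timestamp' must be POSIXct (see read_records())")
  bad <- which(is.na(records$timestamp))
  if (length(bad))
    abort("unparseable timestamp at row %d", bad[1])
  bad <- which(is.na(records$true_label) | records$true_label == "")
  if (length(bad))
    abort("missing true_label at row %d", bad[1])
  for (obs in observers(records)) {
    cc <- conf_col(obs)
    if (cc %in% names(records)) {
      conf <- records[[cc]]
      bad <- which(!is.na(conf) & (conf < 0 | conf > 1))
      if (length(bad))
        abort("confidence outside [0,1] at row %d, column '%s'", bad[1], cc)
    }
  }
  invisible(records)
}

#' Read classification records from CSV
#'
#' Expects the documented dialect: UTF-8 comma-separated values with a header
#' row; `camera_id`, ISO-8601 `timestamp`, optional `trigger_id`,
#' `true_label`, then `<observer>_label` / `<observer>_confidence` pairs.
#' Blank cells are absent optional values; `EMPTY` marks a blank frame and
#' `UNKNOWN` an image whose ground truth could not be resolved.
#'
#' @param path path to the CSV file.
#' @param tz timezone applied to the timestamps (default UTC).
#' @return A validated record `data.frame`.
#' @export
read_records <- function(path, tz = "UTC") {
  if (!file.exists(path)) abort("records file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (col in c("camera_id", "timestamp", "true_label"))
    if (!col %in% names(raw))
      abort("%s: missing required column '%s'", path, col)
  ts <- as.POSIXct(raw$timestamp, tz = tz, format = "%Y-%m-%dT%H:%M:%OS")
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(raw$timestamp[alt], tz = tz,
                        format = "%Y-%m-%d %H:%M:%OS")
  bad <- which(is.na(ts))
  if (length(bad))
    abort("%s: unparseable timestamp at row %d, column 'timestamp'",
          path, bad[1])
  raw$timestamp <- ts
  for (cc in grep("_confidence$", names(raw), value = TRUE)) {
    val <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(nzchar(raw[[cc]]) & is.na(val))
    if (length(bad))
      abort("%s: non-numeric confidence at row %d, column '%s'",
            path, bad[1], cc)
    bad <- which(!is.na(val) & (val < 0 | val > 1))
    if (length(bad))
      abort("%s: confidence outside [0,1] at row %d, column '%s'",
            path, bad[1], cc)
    raw[[cc]] <- val
  }
  for (obs in observers(raw)) {
    lc <- label_col(obs)
    raw[[lc]][!nzchar(raw[[lc]])] <- EMPTY_LABEL
  }
  if ("trigger_id" %in% names(raw))
    raw$trigger_id[!nzchar(raw$trigger_id)] <- NA_character_
  validate_records(raw)
  raw
}

#' Write classification records to CSV
#'
#' Inverse of [read_records()]: timestamps are serialised as ISO-8601 and
#' absent optional values as blank cells, so a write-then-read round trip
#' reproduces the table.
#'
#' @param records a validated record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  out <- records
  out$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# rows usable for scoring: ground truth resolved
scoring_subset <- function(records) {
  records[records$true_label != UNKNOWN_LABEL, , drop = FALSE]
}
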