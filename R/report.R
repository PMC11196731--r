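# Report output: CSV for machines, aligned text tables for people.
# Thousands separators appear only in the text rendering, never in CSV.

format_currency <- function(x) formatC(round(x), format = "d", big.mark = ",")

#' Write a report table to disk
#'
#' Serialises any of the package's report data frames ([compare_scenarios()],
#' [emissions_report()], [comparison_table()], [confidence_histogram()], ...)
#' either as plain CSV (raw numbers, no separators) or as an aligned
#' monospace text table in which currency-like columns gain thousands
#' separators and percentages keep one decimal.
#'
#' @param report a `data.frame`.
#' @param path output file path.
#' @param format `"csv"` or `"table"`.
#' @return `path`, invisibly.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".txt")
#' cmp <- compare_scenarios(data.frame(
#'   scenario = scenario_kinds(), total = c(2666628, 2392290, 519652)))
#' write_report(cmp, tmp, format = "table")
#' cat(readLines(tmp), sep = "\n")
write_report <- function(report, path, format = c("csv", "table")) {
  if (!is.data.frame(report)) abort("report must be a data.frame")
  if (!is.character(format) || !all(format %in% c("csv", "table")))
    abort("unknown report format '%s'", paste(format, collapse = ","))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  writeLines(render_text_table(report), path)
  invisible(path)
}

render_text_table <- function(report) {
  df <- as.data.frame(report)
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      if (grepl("pct|fraction", nm)) sprintf("%.1f", v)
      else if (grepl("cost|saving|total|hardware|consumables|staff|travel|fees|connectivity|kg|km", nm))
        format_currency(v)
      else format(v, trim = TRUE)
    } else if (inherits(v, "POSIXct")) format(v, "%Y-%m-%dT%H:%M:%S")
    else as.character(v)
  })
  widths <- mapply(function(nm, col) max(nchar(c(nm, col))), names(df), cols)
  pad <- function(x, w) formatC(x, width = w)
  header <- paste(mapply(pad, names(df), widths), collapse = "  ")
  rule <- paste(vapply(widths, function(w) strrep("-", w), ""), collapse = "  ")
  rows <- if (nrow(df)) {
    m <- do.call(cbind, Map(pad, cols, as.list(widths)))
    apply(m, 1L, paste, collapse = "  ")
  }
  c(header, rule, rows)
}

#' Write a run manifest
#'
#' Records, next to an output file, everything needed to reproduce it: the
#' package version, the subcommand and its parameters, the seed (if any),
#' MD5 digests of every input file, and a timestamp. Deterministic
#' subcommands re-run with an identical manifest reproduce identical outputs.
#'
#' @param path manifest destination (conventionally `<output>.manifest.json`).
#' @param subcommand name of the operation that produced the output.
#' @param inputs character vector of input file paths to digest.
#' @param parameters named list of the parameters used.
#' @param seed integer seed, or `NULL` for deterministic runs.
#' @return The manifest as a list, invisibly.
#' @export
write_manifest <- function(path, subcommand, inputs = character(0),
                           parameters = list(), seed = NULL) {
  digests <- if (length(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
      abort("manifest input not found: %s", paste(missing, collapse = ", "))
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    tool = "camtrapdecide",
    version = as.character(utils::packageVersion("camtrapdecide")),
    subcommand = subcommand,
    parameters = parameters,
    seed = seed,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
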