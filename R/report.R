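.report_columns <- c("enzyme", "pattern", "less_preferred", "strand",
                     "offset", "matched_seq", "discriminating", "score")

#' Serialise PAM hits to TSV or JSON
#'
#' Output is deterministic for fixed input: stable column order, scores
#' formatted to two decimals, no locale-dependent quoting. The TSV carries
#' a header line even for zero hits; the JSON is an array of objects with
#' the same fields.
#'
#' @param hits A `pam_hits` data.frame (ranked).
#' @param format `"tsv"` or `"json"`.
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_report <- function(hits, format = c("tsv", "json"), destination) {
  format <- match.arg(format)
  df <- as.data.frame(hits)[, .report_columns, drop = FALSE]
  df$score <- sprintf("%.2f", df$score)
  if (format == "tsv") {
    con <- file(destination, open = "wb")
    on.exit(close(con))
    writeLines(paste(.report_columns, collapse = "\t"), con)
    if (nrow(df)) {
      body <- apply(df, 1L, function(r) paste(r, collapse = "\t"))
      writeLines(body, con)
    }
  } else {
    df$less_preferred <- as.logical(df$less_preferred)
    df$discriminating <- as.logical(df$discriminating)
    df$offset <- as.integer(df$offset)
    jsonlite::write_json(df, destination, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(destination)
}

#' Read back a TSV hit report
#'
#' Inverse of [write_report()] for the TSV dialect; used for round-trip
#' checks and downstream tooling.
#'
#' @param path Report path.
#' @return data.frame with the report columns (score numeric).
#' @export
read_report_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  df$less_preferred <- as.logical(df$less_preferred)
  df$discriminating <- as.logical(df$discriminating)
  df$offset <- as.integer(df$offset)
  df$score <- as.numeric(df$score)
  df
}
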