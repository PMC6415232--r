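#' Write a result table to CSV or JSON
#'
#' Serialises a data frame of sweep/solver results with a fixed column
#' order (as given) and floating-point values at 12 significant digits,
#' so that repeated runs of the same configuration produce byte-identical
#' files.  CSV files carry a header row; JSON files hold an array of
#' records.
#'
#' @param rows data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (format == "csv") {
    out <- rows
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        out[[j]] <- ifelse(is.na(rows[[j]]), "NA",
                           trimws(formatC(rows[[j]], digits = 12,
                                          format = "g")))
      }
    }
    utils::write.table(out, file = path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = which(vapply(out, is.character,
                                                              logical(1))),
                       na = "NA")
  } else {
    txt <- jsonlite::toJSON(rows, dataframe = "rows", digits = I(12),
                            na = "null", pretty = TRUE)
    writeLines(txt, path)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return data frame.
#' @export
read_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
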