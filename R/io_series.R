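#' Tabular time series with named columns and units
#'
#' @param data Data frame of numeric columns.
#' @param units Optional named character vector of unit strings per column.
#' @return An object of class `tabular_series`.
#' @export
tabular_series <- function(data, units = NULL) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all series columns must be numeric")
  }
  if (!is.null(units)) {
    bad <- setdiff(names(units), names(data))
    if (length(bad)) stop("units given for unknown columns: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(data = data, units = units), class = "tabular_series")
}

#' Read a delimited time series
#'
#' Accepts comma- or whitespace-delimited text with a header row; the
#' delimiter is sniffed from the header.  Lines starting with `#` are
#' treated as comments.
#'
#' @param path File path.
#' @param columns Optional character vector of required columns; a missing
#'   column is an error naming it.  When given, only these columns are kept,
#'   in this order.
#' @param units Optional named character vector of units to attach.
#' @return A [tabular_series].
#' @export
read_series <- function(path, columns = NULL, units = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- grep("^\\s*#", readLines(path, warn = FALSE),
                value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("'%s' has no header row", path))
  sep <- if (grepl(",", lines[1L], fixed = TRUE)) "," else ""
  if (length(lines) == 1L) {
    nms <- trimws(strsplit(lines[1L], if (sep == ",") "," else "\\s+")[[1L]])
    df <- as.data.frame(matrix(numeric(0), ncol = length(nms)))
    names(df) <- nms
  } else {
    df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                            strip.white = TRUE, check.names = FALSE)
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(df))
    if (length(missing_cols)) {
      stop(sprintf("column(s) not found in '%s': %s", path,
                   paste(missing_cols, collapse = ", ")))
    }
    df <- df[, columns, drop = FALSE]
  }
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  tabular_series(df, units = units)
}

#' Write a tabular series as delimited text
#'
#' @param series A [tabular_series] or plain data frame.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @param meta Optional named list written as `# key: value` comment lines.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path, sep = ",", meta = NULL) {
  df <- if (inherits(series, "tabular_series")) series$data else as.data.frame(series)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
    }
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
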