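#' Write a long results table to TSV
#'
#' Numeric columns are written with 15 significant digits so a
#' write/read round trip preserves them to at least 12 significant
#' digits.
#'
#' @param table a results data frame (e.g. from [fixed_table()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results <- function(table, path) {
  out <- table
  for (j in names(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "g", digits = 15)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a key=value run configuration file
#'
#' Plain-text configuration for the command-line interface: one
#' `key = value` pair per line, `#` comments allowed. Values are kept as
#' strings; callers coerce as needed.
#'
#' @param path file path.
#' @return named list of strings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  setNames(lapply(kv, function(m) trimws(m[[3L]])),
           vapply(kv, function(m) trimws(m[[2L]]), ""))
}
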