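#' Round half away from zero
#'
#' Commercial rounding used for all reported exposure counts: 0.5 always
#' rounds away from zero, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
#' @export
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

# Tab-separated I/O used for every fixture and report table. UTF-8,
# header row, no quoting beyond what embedded tabs would force.
read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""), ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# Split a ";"-delimited field, treating "-" and "" as empty.
split_field <- function(x, sep = ";") {
  lapply(x, function(v) {
    if (is.na(v) || v %in% c("-", "")) character(0)
    else trimws(strsplit(v, sep, fixed = TRUE)[[1]])
  })
}

join_field <- function(x, sep = ";") {
  vapply(x, function(v) if (length(v) == 0) "-" else paste(v, collapse = sep),
         character(1))
}

pkg_extdata <- function(...) {
  system.file("extdata", ..., package = "pgxposure", mustWork = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
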