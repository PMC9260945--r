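# Shared numeric and parsing helpers.

#' Round half away from zero
#'
#' Reported descriptor values follow the chemistry convention of rounding
#' halves away from zero (so 1.90475 -> 1.9048 at 4 digits), unlike base
#' [round()], which rounds halves to even. A small epsilon guards against
#' binary representation error in values that are exact halves in decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_up(1.90475, 4)  # 1.9048
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Normalize minus-sign glyphs
#'
#' Published tables mix ASCII hyphens, Unicode minus signs and en-dashes as
#' negation. All are mapped to the ASCII hyphen so numeric parsing succeeds.
#'
#' @param x Character vector.
#' @return Character vector with all minus-like glyphs as `-`.
#' @export
normalize_minus <- function(x) {
  gsub("[−–—]", "-", x)
}

# Parse a numeric column tolerating unicode minus glyphs and stray
# whitespace; NA entries pass through.
parse_numeric <- function(x) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(trimws(normalize_minus(as.character(x)))))
  bad <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(out)
  if (any(bad)) {
    stop("non-numeric value(s): ", paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  out
}

# Read a TSV/CSV fixture, skipping '#' comment headers.
read_delim_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", fill = FALSE)
}

# Locate a file shipped under inst/extdata.
#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' ip_extdata()
ip_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "ipscreen")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no such extdata file: ", file)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
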