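#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (half-up), the convention used when rendering percentages in reports.
#' Base [round()] uses banker's rounding, which disagrees at exact ties
#' such as 0.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(96.85, 1)   # 96.9
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Percentage of a count over a denominator, half-up rounded
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places kept.
#' @return percentage in `[0, 100]`; `NA` when `den` is 0.
#' @export
pct_of <- function(num, den, digits = 1) {
  out <- round_half_up(100 * num / den, digits)
  out[rep_len(den == 0, length(out))] <- NA_real_
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a CSV file as character columns
#'
#' All columns are read as character so that dialect-specific encodings
#' (dates, gender codes) survive untouched until explicitly parsed.
#' @param path file path.
#' @return data.frame of character columns.
#' @keywords internal
read_csv_raw <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL, fileEncoding = "UTF-8")
}

#' Write a data.frame as RFC-4180 CSV
#' @param df data.frame.
#' @param path output path.
#' @keywords internal
write_csv_plain <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' SHA-256 hash of a file, hex encoded
#' @param path file path.
#' @return 64-character hex string.
#' @export
hash_file <- function(path) {
  digest::digest(file = path, algo = "sha256")
}

# Fixed English month abbreviations: date rendering and parsing must not
# depend on the session locale.
.month_abb <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Format dates in a dialect-specific style
#'
#' Styles: `"dmy_slash"` (dd/mm/yyyy), `"iso"` (yyyy-mm-dd) and
#' `"dmon"` (dd-Mon-yyyy with fixed English month abbreviations).
#' `NA` dates render as the empty string.
#' @param x Date vector.
#' @param style one of `"dmy_slash"`, `"iso"`, `"dmon"`.
#' @return character vector.
#' @export
format_dialect_date <- function(x, style) {
  out <- character(length(x))
  ok <- !is.na(x)
  d <- x[ok]
  out[ok] <- switch(style,
    dmy_slash = format(d, "%d/%m/%Y"),
    iso       = format(d, "%Y-%m-%d"),
    dmon      = {
      lt <- as.POSIXlt(d)
      sprintf("%02d-%s-%04d", lt$mday, .month_abb[lt$mon + 1L],
              lt$year + 1900L)
    },
    stopf("unknown date style: %s", style))
  out
}

#' Parse dialect-formatted date strings
#'
#' Invalid calendar dates (e.g. 31/02/2020) and empty strings yield `NA`.
#' Parsing is strict: the rendered form of the parsed date must equal the
#' input, so "31/02/2020" is not silently rolled over to March.
#' @param x character vector.
#' @param style one of `"dmy_slash"`, `"iso"`, `"dmon"`.
#' @return Date vector with `NA` for unparseable entries.
#' @export
parse_dialect_date <- function(x, style) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  nonempty <- !is.na(x) & nzchar(x)
  if (!any(nonempty)) return(out)
  xi <- x[nonempty]
  d <- switch(style,
    dmy_slash = as.Date(xi, format = "%d/%m/%Y"),
    iso       = as.Date(xi, format = "%Y-%m-%d"),
    dmon      = {
      parts <- regmatches(xi, regexec("^(\\d{1,2})-([A-Za-z]{3})-(\\d{4})$", xi))
      vapply(parts, function(p) {
        if (length(p) != 4L) return(NA_real_)
        mon <- match(p[3], .month_abb)
        if (is.na(mon)) return(NA_real_)
        as.numeric(as.Date(sprintf("%s-%02d-%02d", p[4], mon,
                                   as.integer(p[2])),
                           format = "%Y-%m-%d"))
      }, numeric(1)) |> as.Date(origin = "1970-01-01")
    },
    stopf("unknown date style: %s", style))
  # reject dates that only parsed by rollover (e.g. 31 Feb -> 2 Mar)
  rendered <- format_dialect_date(d, style)
  bad <- !is.na(d) & rendered != xi
  # allow inputs without zero padding ("5/3/2020")
  if (any(bad)) {
    reparse <- format_dialect_date(d[bad], style)
    loose_in <- gsub("(^|[-/])0", "\\1", xi[bad])
    loose_re <- gsub("(^|[-/])0", "\\1", reparse)
    bad[bad] <- loose_in != loose_re
  }
  d[bad] <- NA
  out[nonempty] <- d
  out
}

#' Write an object as pretty JSON
#' @param x object serialisable by jsonlite.
#' @param path output path.
#' @keywords internal
write_json_file <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
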