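# Calendar-month arithmetic. Months are "YYYY-MM" keys throughout the
# package; all window logic is month-granular, so months are converted to a
# linear index (months since 0000-01) and back.

#' Month keys
#'
#' Reports are counted per calendar month of their receive date, so every
#' time axis in the package is a sequence of `"YYYY-MM"` keys. These helpers
#' convert between keys, dates and a linear month index.
#'
#' @param x a character vector of `"YYYY-MM"` keys, or a `Date` for
#'   `as_month()`.
#' @param from,to month keys delimiting an inclusive span.
#' @param k integer number of months to shift by (may be negative).
#' @param i integer month index as produced by `month_index()`.
#'
#' @return `as_month()` and `month_add()` return `"YYYY-MM"` keys;
#'   `month_index()` an integer vector; `month_seq()` the inclusive sequence
#'   of keys from `from` to `to`.
#'
#' @examples
#' as_month(as.Date("2010-08-23"))
#' month_add("2010-01", -3)
#' month_seq("2009-11", "2010-02")
#' @name months
NULL

#' @rdname months
#' @export
as_month <- function(x) {
  if (inherits(x, "Date")) return(format(x, "%Y-%m"))
  x <- as.character(x)
  bad <- !is.na(x) & !grepl("^\\d{4}-(0[1-9]|1[0-2])$", x)
  if (any(bad)) {
    stop("invalid month key(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname months
#' @export
month_index <- function(x) {
  x <- as_month(x)
  yr <- as.integer(substr(x, 1, 4))
  mo <- as.integer(substr(x, 6, 7))
  yr * 12L + (mo - 1L)
}

#' @rdname months
#' @export
month_from_index <- function(i) {
  i <- as.integer(i)
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' @rdname months
#' @export
month_add <- function(x, k) month_from_index(month_index(x) + as.integer(k))

#' @rdname months
#' @export
month_seq <- function(from, to) {
  a <- month_index(from)
  b <- month_index(to)
  if (b < a) stop("empty month span: ", from, " .. ", to, call. = FALSE)
  month_from_index(seq.int(a, b))
}
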