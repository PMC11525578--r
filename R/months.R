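#' Month sequence utilities
#'
#' Monthly series are indexed by (year, month) pairs throughout the package.
#' Internally a month is mapped to the integer `year * 12 + (month - 1)` so
#' that spans, gaps and alignment checks reduce to integer arithmetic.
#'
#' @param year,month integer vectors of equal length.
#' @return `month_index()` returns an integer vector; `month_seq()` a
#'   data.frame with columns `year` and `month` covering the closed span.
#' @keywords internal
month_index <- function(year, month) {
  stopifnot(all(month >= 1L & month <= 12L))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' @param from,to length-2 integer vectors `c(year, month)`, inclusive.
#' @rdname month_index
#' @export
month_seq <- function(from, to) {
  i0 <- month_index(from[1], from[2])
  i1 <- month_index(to[1], to[2])
  if (i1 < i0) stop("month span end precedes its start", call. = FALSE)
  idx <- seq.int(i0, i1)
  data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
}

#' @param months a data.frame with `year` and `month` columns.
#' @rdname month_index
#' @keywords internal
assert_consecutive_months <- function(months) {
  idx <- month_index(months$year, months$month)
  if (length(idx) == 0L) stop("empty month list", call. = FALSE)
  d <- diff(idx)
  if (any(d != 1L)) {
    bad <- which(d != 1L)[1]
    stop(sprintf("months are not consecutive: gap after %d-%02d",
                 months$year[bad], months$month[bad]), call. = FALSE)
  }
  invisible(idx)
}

#' Format (year, month) pairs as "YYYY-MM" labels
#' @keywords internal
month_label <- function(year, month) sprintf("%d-%02d", year, month)
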