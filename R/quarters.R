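#' Calendar quarter of a date
#'
#' Maps months 1-3 to Q1, 4-6 to Q2, 7-9 to Q3, and 10-12 to Q4. The quarterly
#' reporting period is the clustering unit of the mixed model, so every case
#' carries a (year, quarter) pair.
#'
#' @param date A `Date` vector or character vector parseable as `YYYY-MM-DD`.
#' @return A tibble with integer columns `year` and `quarter`.
#' @examples
#' quarter_of("2010-01-15")
#' @export
quarter_of <- function(date) {
  d <- tryCatch(as.Date(date),
                error = function(e) rep(as.Date(NA), length(date)))
  if (anyNA(d)) {
    bad <- date[is.na(d)]
    abort(sprintf("unparseable date(s): %s",
                  paste(head(unique(as.character(bad)), 5), collapse = ", ")))
  }
  tibble::tibble(
    year = as.integer(format(d, "%Y")),
    quarter = (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L
  )
}

#' Parse a quarter label such as "2010Q1"
#'
#' @param x Character vector of `YYYYQn` labels.
#' @return A tibble with columns `year` and `quarter`.
#' @export
parse_quarter <- function(x) {
  m <- regexec("^([0-9]{4})Q([1-4])$", as.character(x))
  g <- regmatches(as.character(x), m)
  if (any(lengths(g) != 3)) {
    abort(sprintf("malformed quarter label(s): %s",
                  paste(x[lengths(g) != 3], collapse = ", ")))
  }
  tibble::tibble(year = as.integer(vapply(g, `[`, "", 2)),
                 quarter = as.integer(vapply(g, `[`, "", 3)))
}

quarter_label <- function(year, quarter) sprintf("%04dQ%d", year, quarter)

#' Study window of quarterly periods
#'
#' A closed range of quarters defining which cases are analyzed and the
#' sequential (ordinal) index of each quarter. The default window,
#' 2010Q1-2015Q1, spans 21 quarters.
#'
#' @param start,end Quarter labels (`"YYYYQn"`).
#' @return A `pv_window` list with `start`, `end`, and `n_quarters`.
#' @examples
#' study_window()$n_quarters
#' @export
study_window <- function(start = "2010Q1", end = "2015Q1") {
  s <- parse_quarter(start)
  e <- parse_quarter(end)
  s_lin <- s$year * 4L + s$quarter
  e_lin <- e$year * 4L + e$quarter
  if (s_lin > e_lin) abort("study window start is after its end")
  structure(list(start = s, end = e, n_quarters = e_lin - s_lin + 1L),
            class = "pv_window")
}

#' Ordinal quarter index within a study window
#'
#' @param year,quarter Integer vectors.
#' @param window A [study_window()]; its first quarter has ordinal 1.
#' @return Integer vector of ordinals (may fall outside `1..n_quarters` for
#'   quarters outside the window).
#' @export
quarter_ordinal <- function(year, quarter, window = study_window()) {
  (year * 4L + quarter) - (window$start$year * 4L + window$start$quarter) + 1L
}

#' Quarters of a study window, in order
#'
#' @param window A [study_window()].
#' @return A tibble with `year`, `quarter`, `ordinal`, and `label`.
#' @export
window_quarters <- function(window = study_window()) {
  lin <- seq(window$start$year * 4L + window$start$quarter,
             window$end$year * 4L + window$end$quarter)
  year <- (lin - 1L) %/% 4L
  quarter <- lin - year * 4L
  tibble::tibble(year = as.integer(year), quarter = as.integer(quarter),
                 ordinal = seq_along(lin),
                 label = quarter_label(year, quarter))
}
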