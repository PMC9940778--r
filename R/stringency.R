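#' Simulate a policy stringency index
#'
#' Builds a piecewise-constant stringency series (OxCGRT-style, 0-100) from a
#' list of `(start_date, level)` breakpoints. Each date takes the level of the
#' most recent breakpoint at or before it; dates before the first breakpoint
#' take the first level.
#'
#' @param dates Vector of `Date`s (non-empty, any order; returned sorted).
#' @param breakpoints A data frame with columns `start_date` and `level`, or a
#'   named numeric vector with ISO dates as names.
#' @return A tibble with columns `date`, `stringency` (values in `[0, 100]`).
#' @export
#' @examples
#' simulate_stringency(as.Date("2020-03-01") + 0:9,
#'                     data.frame(start_date = as.Date("2020-03-01"), level = 80))
simulate_stringency <- function(dates, breakpoints) {
  if (length(dates) == 0) abort("`dates` must be non-empty.")
  dates <- sort(as.Date(dates))
  if (is.numeric(breakpoints) && !is.null(names(breakpoints))) {
    breakpoints <- data.frame(start_date = as.Date(names(breakpoints)),
                              level = unname(breakpoints))
  }
  if (!all(c("start_date", "level") %in% names(breakpoints)) ||
      nrow(breakpoints) == 0)
    abort("`breakpoints` needs columns `start_date` and `level` (>= 1 row).")
  if (any(breakpoints$level < 0 | breakpoints$level > 100))
    abort("Stringency levels must lie in [0, 100].")
  bp <- dplyr::arrange(tibble::as_tibble(breakpoints), .data$start_date)
  ix <- findInterval(as.numeric(dates), as.numeric(bp$start_date))
  ix[ix == 0] <- 1L # before first breakpoint: carry the first level back
  tibble::tibble(date = dates, stringency = pmin(100, pmax(0, bp$level[ix])))
}

#' Read a stringency series from CSV
#'
#' Accepts any CSV with `date` and `value` (or `stringency`) columns, e.g. an
#' OxCGRT extract.
#'
#' @param path CSV path.
#' @return A tibble with columns `date`, `stringency`.
#' @export
read_stringency_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  val <- intersect(c("stringency", "value"), names(x))[1]
  if (!"date" %in% names(x) || is.na(val))
    abort("Stringency CSV needs columns `date` and `value` (or `stringency`).")
  out <- tibble::tibble(date = as.Date(x$date), stringency = as.numeric(x[[val]]))
  if (any(out$stringency < 0 | out$stringency > 100, na.rm = TRUE))
    abort("Stringency values must lie in [0, 100].")
  dplyr::arrange(out, .data$date)
}
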