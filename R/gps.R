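#' Default activity-to-place category map
#'
#' Maps the nine activity categories (plus `"home"`) onto the six place
#' categories of Community Mobility Reports: food and medicine trips show up at
#' grocery stores and pharmacies, non-food shopping and meeting friends at
#' retail and recreation, work at workplaces, sports / pets / boredom outings
#' at parks, everything else at transit stations, and home time as residential.
#'
#' @return Named character vector (names: activities + `"home"`).
#' @export
default_category_map <- function() {
  c(food = "grocery_and_pharmacy", medicine = "grocery_and_pharmacy",
    nonfood = "retail_and_recreation", friends = "retail_and_recreation",
    work = "workplaces", sports = "parks", pets = "parks", boredom = "parks",
    other = "transit_stations", home = "residential")
}

#' Observe stays as place visits
#'
#' Emulates an opt-in location-history service: each opted-in person's stays
#' become place visits in the mapped category, keeping the stay's duration.
#'
#' @param stays Stays tibble from [simulate_stays()].
#' @param category_map Named character vector mapping every activity category
#'   (and `"home"`) to one of [place_categories()].
#' @param optin_prob Probability a person has location history enabled, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble `device_id`, `place_category`, `date`, `duration_h`.
#' @export
observe_place_visits <- function(stays, category_map = default_category_map(),
                                 optin_prob = 1, seed = 1) {
  if (optin_prob < 0 || optin_prob > 1) abort("`optin_prob` must be in [0, 1].")
  unmapped <- setdiff(unique(stays$category), names(category_map))
  if (length(unmapped) > 0)
    abort(paste0("No place category mapped for activity: ",
                 paste(unmapped, collapse = ", ")))
  if (!all(category_map %in% place_categories()))
    abort("`category_map` values must be the six place categories.")
  set.seed(as.integer(seed))
  ids <- sort(unique(stays$person_id))
  optin <- ids[runif(length(ids)) <= optin_prob]
  stays |>
    dplyr::filter(.data$person_id %in% optin) |>
    dplyr::transmute(device_id = .data$person_id,
                     place_category = unname(category_map[.data$category]),
                     date = .data$date, duration_h = .data$duration_h)
}

#' Daily per-category visit measure
#'
#' Blends the two readings of "visits and length of stay":
#' `alpha * (visit count) + (1 - alpha) * (total duration in hours)` per place
#' category and date. Dates in the observed range with no visits count as 0.
#'
#' @param visits Tibble from [observe_place_visits()].
#' @param alpha Mixing weight in `[0, 1]` (1 = pure counts, 0 = pure duration).
#' @return Tibble `place_category`, `date`, `value`, complete over the six
#'   categories x observed date range.
#' @export
daily_category_measure <- function(visits, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1].")
  if (nrow(visits) == 0)
    return(tibble::tibble(place_category = character(), date = as.Date(character()),
                          value = numeric()))
  grid <- tidyr::expand_grid(
    place_category = place_categories(),
    date = seq(min(visits$date), max(visits$date), by = "day"))
  visits |>
    dplyr::group_by(.data$place_category, .data$date) |>
    dplyr::summarise(value = alpha * dplyr::n() + (1 - alpha) * sum(.data$duration_h),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("place_category", "date")) |>
    dplyr::mutate(value = tidyr::replace_na(.data$value, 0)) |>
    dplyr::arrange(.data$place_category, .data$date)
}

#' Day-of-week baseline for percent changes
#'
#' The CMR baseline: per place category and day of week, the median of the
#' daily values over a window that contains exactly five of each weekday
#' (e.g. 2020-01-03 to 2020-02-06).
#'
#' @param daily Tibble from [daily_category_measure()].
#' @param window_start,window_end Window `Date`s (inclusive).
#' @return Tibble `place_category`, `wday` (1 = Monday), `baseline` (42 rows).
#' @export
compute_baseline <- function(daily, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  win <- seq(window_start, window_end, by = "day")
  wd <- as.integer(format(win, "%u"))
  if (length(win) != 35 || !all(tabulate(wd, 7) == 5))
    abort("Baseline window must contain exactly five of each day of week.")
  sub <- dplyr::filter(daily, .data$date >= window_start, .data$date <= window_end)
  if (dplyr::n_distinct(sub$date) != 35)
    abort("Daily measures do not cover the whole baseline window.")
  sub |>
    dplyr::mutate(wday = as.integer(format(.data$date, "%u"))) |>
    dplyr::group_by(.data$place_category, .data$wday) |>
    dplyr::summarise(baseline = stats::median(.data$value), .groups = "drop")
}

#' Percent change versus a day-of-week baseline
#'
#' `100 * (value - baseline) / baseline` against the matching category x
#' day-of-week baseline cell; a zero baseline yields `NA` (never +-Inf).
#'
#' @param daily Tibble from [daily_category_measure()].
#' @param baseline Tibble from [compute_baseline()].
#' @return `daily` with columns `wday`, `baseline`, `pct_change`.
#' @export
percent_change_vs_baseline <- function(daily, baseline) {
  daily |>
    dplyr::mutate(wday = as.integer(format(.data$date, "%u"))) |>
    dplyr::left_join(baseline, by = c("place_category", "wday")) |>
    dplyr::mutate(pct_change = dplyr::if_else(
      !is.na(.data$baseline) & .data$baseline > 0,
      100 * (.data$value - .data$baseline) / .data$baseline,
      NA_real_))
}

#' Composite six-category GPS index
#'
#' Additive index over the six place categories' percent changes per date. Any
#' missing component makes the composite missing (the sum is never silently
#' rescaled). `invert_residential` flips the sign of the residential component
#' (more time at home = less mobility); the default keeps the literal additive
#' index over all six categories.
#'
#' @param pct Tibble from [percent_change_vs_baseline()].
#' @param invert_residential Logical flag (default `FALSE`).
#' @return Tibble `date`, `composite`.
#' @export
composite_gps_index <- function(pct, invert_residential = FALSE) {
  pct |>
    dplyr::mutate(signed = dplyr::if_else(
      invert_residential & .data$place_category == "residential",
      -.data$pct_change, .data$pct_change)) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      composite = if (sum(!is.na(.data$signed)) == 6) sum(.data$signed) else NA_real_,
      .groups = "drop")
}

cmr_pct_cols <- function() {
  paste0(c("retail_and_recreation", "grocery_and_pharmacy", "parks",
           "transit_stations", "workplaces", "residential"),
         "_percent_change_from_baseline")
}

cmr_header <- function() {
  c("country_region_code", "country_region", "sub_region_1", "sub_region_2",
    "metro_area", "iso_3166_2_code", "census_fips_code", "place_id", "date",
    cmr_pct_cols())
}

#' Read / write Community Mobility Report CSVs
#'
#' Bit-faithful reader and writer for the published Google CMR CSV dialect
#' (header `country_region_code, ..., date,
#' retail_and_recreation_percent_change_from_baseline, ...`). Empty cells are
#' preserved as missing; a write-read round trip is value-identical.
#'
#' @param path CSV path.
#' @param records Tibble with at least `date` and the six
#'   `*_percent_change_from_baseline` columns; absent region-identifier columns
#'   are written empty.
#' @return `read_cmr_csv()` returns a tibble with the full CMR header;
#'   `write_cmr_csv()` returns `path` invisibly.
#' @export
read_cmr_csv <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(c("date", cmr_pct_cols()), hdr)
  if (length(miss) > 0)
    abort(paste0("Not a Community Mobility Report CSV; missing column(s): ",
                 paste(miss, collapse = ", ")))
  spec <- readr::cols(.default = readr::col_character(),
                      date = readr::col_date())
  for (cc in cmr_pct_cols()) spec$cols[[cc]] <- readr::col_double()
  readr::read_csv(path, col_types = spec)
}

#' @rdname read_cmr_csv
#' @export
write_cmr_csv <- function(records, path) {
  miss <- setdiff(c("date", cmr_pct_cols()), names(records))
  if (length(miss) > 0)
    abort(paste0("Records are missing column(s): ", paste(miss, collapse = ", ")))
  out <- tibble::as_tibble(records)
  for (cc in setdiff(cmr_header(), names(out))) out[[cc]] <- NA_character_
  out <- out[, cmr_header()]
  readr::write_csv(out, path, na = "")
  invisible(path)
}
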