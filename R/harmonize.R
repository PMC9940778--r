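#' Weekly aggregation of a daily series
#'
#' Mean of the available daily values per ISO week (Monday start). Any column
#' other than `date` and `value` is treated as a grouping column. Weeks with
#' fewer than `min_days` non-missing days are set to `NA`.
#'
#' @param daily Tibble with columns `date`, `value` and optional grouping
#'   columns.
#' @param min_days Minimum non-missing days per week (default 4).
#' @return Tibble with grouping columns, `week`, `value`, `n_days`.
#' @export
weekly_aggregate <- function(daily, min_days = 4) {
  stopifnot(all(c("date", "value") %in% names(daily)))
  by <- setdiff(names(daily), c("date", "value"))
  daily |>
    dplyr::mutate(week = iso_week_start(.data$date)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "week")))) |>
    dplyr::summarise(n_days = sum(!is.na(.data$value)),
                     value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(value = dplyr::if_else(.data$n_days >= min_days,
                                         .data$value, NA_real_)) |>
    dplyr::relocate("week", "value", "n_days", .after = dplyr::last_col())
}

#' Relative change versus a baseline week
#'
#' Anchors a weekly level series to a common baseline week:
#' `100 * (v_t - v_base) / v_base` per group, so the baseline week maps to
#' exactly 0 and heterogeneous channel scales become comparable.
#'
#' @param weekly Tibble with `week`, `value` and optional grouping columns.
#' @param baseline_week `Date` of the baseline week's Monday.
#' @return `weekly` plus a `rel_change_pct` column.
#' @export
relative_change_from_baseline <- function(weekly, baseline_week) {
  stopifnot(all(c("week", "value") %in% names(weekly)))
  baseline_week <- as.Date(baseline_week)
  by <- setdiff(names(weekly), c("week", "value", "n_days"))
  grouped <- weekly |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)))
  out <- grouped |>
    dplyr::mutate(.base = .data$value[match(baseline_week, .data$week)]) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::filter(is.na(.data$.base) | .data$.base == 0) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(by)))
  if (nrow(bad) > 0) {
    lab <- if (length(by) > 0)
      paste(apply(as.data.frame(bad), 1, paste, collapse = "/"), collapse = "; ")
    else "(ungrouped series)"
    abort(paste0("Baseline week ", format(baseline_week),
                 " missing or zero for: ", lab))
  }
  out |>
    dplyr::mutate(rel_change_pct = 100 * (.data$value - .data$.base) / .data$.base) |>
    dplyr::select(-".base")
}

#' Match weekly series to survey waves
#'
#' Keeps only the weeks that are a wave's field week and labels them with the
#' wave number, producing the wave-aligned comparison panel. Waves whose field
#' week is absent from the series are dropped (with a warning naming them).
#'
#' @param weekly Tibble with `week` and any value/grouping columns.
#' @param schedule Tibble from [wave_schedule()].
#' @return `weekly` restricted to field weeks, with `wave` and `week_start`
#'   columns.
#' @export
match_to_waves <- function(weekly, schedule) {
  out <- weekly |>
    dplyr::inner_join(dplyr::select(schedule, "wave", week = "start_date"),
                      by = "week") |>
    dplyr::rename(week_start = "week") |>
    dplyr::relocate("wave", "week_start")
  missing_waves <- setdiff(schedule$wave, out$wave)
  if (length(missing_waves) > 0)
    warn(paste0("No weekly data for wave(s): ",
                paste(missing_waves, collapse = ", ")))
  out
}

#' Centered moving average of a daily series
#'
#' Smooths each group's daily values with a centered window; positions whose
#' window is incomplete (series edges) become `NA`.
#'
#' @param daily Tibble with `date`, `value` and optional grouping columns.
#' @param window Odd window length (default 7).
#' @return `daily` with `value` replaced by the smoothed series.
#' @export
moving_average <- function(daily, window = 7) {
  if (window %% 2 != 1 || window < 1) abort("`window` must be odd and >= 1.")
  by <- setdiff(names(daily), c("date", "value"))
  daily |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::mutate(value = as.numeric(stats::filter(.data$value,
                                                   rep(1 / window, window),
                                                   sides = 2))) |>
    dplyr::ungroup()
}
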