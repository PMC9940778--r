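#' Default stringency breakpoints
#'
#' A piecewise-constant containment-policy profile shaped like Austria's
#' 2020-2021 course: low in January/February, a hard first lockdown in
#' mid-March, stepwise re-opening over the summer, tightening from September,
#' a second and third lockdown in November/December, and a slow spring easing.
#'
#' @return Tibble `start_date`, `level`.
#' @export
default_stringency_breakpoints <- function() {
  tibble::tibble(
    start_date = as.Date(c("2019-12-30", "2020-03-16", "2020-05-04",
                           "2020-06-15", "2020-07-01", "2020-09-14",
                           "2020-11-03", "2020-11-17", "2020-12-07",
                           "2020-12-26", "2021-02-08")),
    level = c(5, 85, 60, 45, 35, 48, 72, 85, 68, 82, 68))
}

#' Build a pipeline run configuration
#'
#' Collects every parameter of an end-to-end run: the population, the latent
#' model, the stringency profile, per-channel observation parameters, the wave
#' schedule, weighting targets, the baseline week, and analysis toggles. All
#' randomness derives from `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param n_persons Population size (default 500).
#' @param start_date First simulated day, a Monday (default 2019-12-30 so the
#'   GPS baseline window Jan 3 - Feb 6, 2020 is covered).
#' @param n_weeks Number of simulated ISO weeks (default 62, covering all 22
#'   waves through early March 2021).
#' @param population Optional [population_spec()] (default built from
#'   `n_persons`).
#' @param model A [latent_mobility_model()].
#' @param stringency_breakpoints Tibble `start_date`, `level`.
#' @param gsm List: `spacing_km`, `event_rate_per_hour`, `coverage_prob`.
#' @param gps List: `optin_prob`, `alpha`, `baseline_start`, `baseline_end`,
#'   `invert_residential`.
#' @param survey List of [response_model()] arguments plus `panel_size`.
#' @param schedule Tibble from [wave_schedule()].
#' @param targets Weighting margin targets (default: the population margins).
#' @param baseline_week Monday of the common baseline week (default
#'   2020-03-23, the wave-1 field week).
#' @param min_days Weekly completeness rule (default 4).
#' @param use_moving_average Smooth daily channel series with a centered 7-day
#'   moving average before the wave alignment (default `FALSE`).
#' @param lockdown_date Partial-lockdown date for the DiD check (default
#'   2020-11-03).
#' @param did_window_weeks Half-width of the DiD pre/post windows in weeks
#'   (default 8).
#' @return Object of class `mob_run_config`.
#' @export
run_config <- function(seed,
                       n_persons = 500,
                       start_date = as.Date("2019-12-30"),
                       n_weeks = 62,
                       population = NULL,
                       model = default_latent_model(),
                       stringency_breakpoints = default_stringency_breakpoints(),
                       gsm = list(),
                       gps = list(),
                       survey = list(),
                       schedule = wave_schedule(),
                       targets = NULL,
                       baseline_week = as.Date("2020-03-23"),
                       min_days = 4,
                       use_moving_average = FALSE,
                       lockdown_date = as.Date("2020-11-03"),
                       did_window_weeks = 8) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort("`seed` is mandatory and must be a single integer.")
  start_date <- as.Date(start_date)
  if (as.integer(format(start_date, "%u")) != 1)
    abort("`start_date` must be a Monday (ISO weeks).")
  population <- population %||% population_spec(n_persons)
  gsm <- utils::modifyList(
    list(spacing_km = 0.75, event_rate_per_hour = 1, coverage_prob = 0.7), gsm)
  gps <- utils::modifyList(
    list(optin_prob = 0.6, alpha = 0.5,
         baseline_start = as.Date("2020-01-03"),
         baseline_end = as.Date("2020-02-06"),
         invert_residential = FALSE), gps)
  survey <- utils::modifyList(
    list(panel_size = min(300, population$n_persons), recall_noise_sd = 0.7,
         desirability_shift = 0, desirability_stringency_slope = 0,
         item_nonresponse_prob = 0.01, attrition_prob = 0.04), survey)
  targets <- targets %||% population$margins
  dates <- seq(start_date, by = "day", length.out = n_weeks * 7)
  baseline_week <- as.Date(baseline_week)
  for (d in list(schedule$start_date, schedule$end_date, baseline_week,
                 as.Date(gps$baseline_start), as.Date(gps$baseline_end)))
    if (any(d < min(dates)) || any(d > max(dates)))
      abort("A referenced date (schedule, baseline week, or GPS baseline window) lies outside the simulated range.")
  if (!baseline_week %in% schedule$start_date)
    abort("`baseline_week` must be one of the wave field weeks.")
  structure(
    list(seed = as.integer(seed), n_persons = population$n_persons,
         start_date = start_date, n_weeks = n_weeks, dates = dates,
         population = population, model = model,
         stringency_breakpoints = stringency_breakpoints,
         gsm = gsm, gps = gps, survey = survey, schedule = schedule,
         targets = targets, baseline_week = baseline_week,
         min_days = min_days, use_moving_average = isTRUE(use_moving_average),
         lockdown_date = as.Date(lockdown_date),
         did_window_weeks = did_window_weeks),
    class = "mob_run_config")
}

#' @export
print.mob_run_config <- function(x, ...) {
  cat(sprintf("<run config> seed %d: %d persons, %d weeks from %s; %d waves; baseline week %s\n",
              x$seed, x$n_persons, x$n_weeks, format(x$start_date),
              nrow(x$schedule), format(x$baseline_week)))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Flat YAML with the scalar fields of [run_config()] plus optional `gsm`,
#' `gps`, `survey` blocks and a `stringency` list of `start_date: level`
#' entries; unspecified fields take the defaults.
#'
#' @param path YAML path.
#' @return A `mob_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("Config must set `seed`.")
  args <- list(seed = y$seed)
  for (f in c("n_persons", "n_weeks", "min_days", "use_moving_average",
              "did_window_weeks"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  for (f in c("start_date", "baseline_week", "lockdown_date"))
    if (!is.null(y[[f]])) args[[f]] <- as.Date(y[[f]])
  for (f in c("gsm", "gps", "survey"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$stringency))
    args$stringency_breakpoints <- tibble::tibble(
      start_date = as.Date(names(y$stringency)),
      level = as.numeric(unlist(y$stringency)))
  do.call(run_config, args)
}

## serializable snapshot of a config (scalars + blocks) for the run directory
config_to_yaml <- function(config, path) {
  y <- list(
    seed = config$seed, n_persons = config$n_persons,
    start_date = format(config$start_date), n_weeks = config$n_weeks,
    baseline_week = format(config$baseline_week), min_days = config$min_days,
    use_moving_average = config$use_moving_average,
    lockdown_date = format(config$lockdown_date),
    did_window_weeks = config$did_window_weeks,
    gsm = config$gsm,
    gps = purrr::map(config$gps, function(v) if (inherits(v, "Date")) format(v) else v),
    survey = config$survey,
    stringency = setNames(as.list(config$stringency_breakpoints$level),
                          format(config$stringency_breakpoints$start_date)))
  yaml::write_yaml(y, path)
  invisible(path)
}
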