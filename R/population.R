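#' Specify a synthetic population
#'
#' Defines the size and demographic composition of the simulated population.
#' Margins are target proportions per weighting variable; in quota mode
#' [generate_population()] hits them exactly via largest-remainder rounding,
#' mimicking a quota-sampled access panel.
#'
#' @param n_persons Number of persons (positive integer).
#' @param margins Named list of named proportion vectors, one per demographic
#'   variable (defaults: `age_group`, `gender`, `region`). Each vector must sum
#'   to 1.
#' @param employment_rate_by_age Named vector of employment proportions per age
#'   group; persons in work get a fixed workplace location.
#' @param region_size_km Side length of each (square) region's bounding box in
#'   km; regions are laid out side by side on a planar grid.
#' @param quota If `TRUE` (default), demographic counts equal the
#'   largest-remainder rounding of margin x n; if `FALSE`, levels are drawn
#'   i.i.d. from the margins.
#' @return An object of class `mob_population_spec`.
#' @export
#' @examples
#' spec <- population_spec(100)
#' pop <- generate_population(spec, seed = 1)
#' table(pop$gender)
population_spec <- function(n_persons,
                            margins = list(
                              age_group = c("14-29" = 0.26, "30-59" = 0.52, "60-74" = 0.22),
                              gender = c(female = 0.5, male = 0.5),
                              region = c(east = 0.44, south = 0.24, west = 0.32)
                            ),
                            employment_rate_by_age = c("14-29" = 0.55, "30-59" = 0.82, "60-74" = 0.12),
                            region_size_km = 100,
                            quota = TRUE) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 1 ||
      n_persons != round(n_persons))
    abort("`n_persons` must be a positive integer.")
  if (!is.list(margins) || is.null(names(margins)))
    abort("`margins` must be a named list of proportion vectors.")
  purrr::iwalk(margins, check_margin)
  if (!"age_group" %in% names(margins))
    abort("`margins` must include an `age_group` variable.")
  missing_emp <- setdiff(names(margins$age_group), names(employment_rate_by_age))
  ## age groups without a stated employment rate default to 0 (e.g. "75+")
  if (length(missing_emp) > 0)
    employment_rate_by_age[missing_emp] <- 0
  if (any(employment_rate_by_age < 0 | employment_rate_by_age > 1))
    abort("`employment_rate_by_age` must lie in [0, 1].")
  stopifnot(region_size_km > 0)
  structure(
    list(n_persons = as.integer(n_persons), margins = margins,
         employment_rate_by_age = employment_rate_by_age,
         region_size_km = region_size_km, quota = isTRUE(quota)),
    class = "mob_population_spec"
  )
}

#' @export
print.mob_population_spec <- function(x, ...) {
  cat("<population spec>", x$n_persons, "persons,",
      if (x$quota) "quota" else "probabilistic", "sampling\n")
  for (v in names(x$margins))
    cat(" ", v, ":", paste(sprintf("%s=%.2f", names(x$margins[[v]]),
                                   x$margins[[v]]), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic population
#'
#' Creates one row per person with demographics drawn from the spec's margins
#' (exactly, in quota mode), a home location uniform in the person's region
#' bounding box, an employment indicator, and — for employed persons — a fixed
#' workplace at a lognormal commute distance from home.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; the population is a deterministic function of
#'   `(spec, seed)`.
#' @param commute_logmean,commute_logsd Lognormal commute-distance parameters
#'   (km, log scale).
#' @return A tibble with columns `person_id`, `age_group`, `gender`, `region`,
#'   `home_x_km`, `home_y_km`, `employed`, `work_x_km`, `work_y_km` (NA when
#'   not employed).
#' @export
generate_population <- function(spec, seed, commute_logmean = log(8),
                                commute_logsd = 0.6) {
  stopifnot(inherits(spec, "mob_population_spec"))
  n <- spec$n_persons
  set.seed(as.integer(seed))

  draw_var <- function(margin) {
    lv <- names(margin)
    if (spec$quota) {
      counts <- largest_remainder(n, margin)
      sample(rep(lv, counts), n)
    } else {
      sample(lv, n, replace = TRUE, prob = margin)
    }
  }
  demo <- purrr::map(spec$margins, draw_var)

  pop <- tibble::tibble(person_id = seq_len(n), !!!demo)

  ## regions tile the plane side by side along x
  rs <- spec$region_size_km
  region_levels <- names(spec$margins$region %||% c(all = 1))
  if (!"region" %in% names(pop)) pop$region <- region_levels[1]
  region_ix <- match(pop$region, region_levels) - 1L
  pop$home_x_km <- region_ix * rs + runif(n, 0, rs)
  pop$home_y_km <- runif(n, 0, rs)

  ## employment: quota within age group so rates are exact where possible
  emp <- logical(n)
  for (ag in unique(pop$age_group)) {
    ix <- which(pop$age_group == ag)
    rate <- unname(spec$employment_rate_by_age[ag])
    k <- unname(largest_remainder(length(ix), c(yes = rate, no = 1 - rate))[1])
    emp[sample(ix, k)] <- TRUE
  }
  pop$employed <- emp

  theta <- runif(n, 0, 2 * pi)
  d <- rlnorm(n, commute_logmean, commute_logsd)
  pop$work_x_km <- ifelse(emp, pop$home_x_km + d * cos(theta), NA_real_)
  pop$work_y_km <- ifelse(emp, pop$home_y_km + d * sin(theta), NA_real_)
  pop
}
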