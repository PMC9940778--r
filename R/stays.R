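#' Latent mobility model
#'
#' Parameterises the latent activity process that drives all three observation
#' channels. For person in age group `g`, on day `t` with stringency `S(t)`,
#' the number of trips for activity category `c` is
#' `Poisson(lambda)` with
#' `log lambda = log base_rate[c, g] + stringency_coef[c] * S(t) + seasonal(t) + eps(t)`,
#' where `seasonal(t) = seasonal_amplitude * cos(2 * pi * (doy - 196) / 365)`
#' (summer peak) and `eps(t) ~ Normal(0, noise_sd)` is a day-level shock shared
#' across categories within a person-day.
#'
#' @param base_rate Either a named numeric vector of expected trips/day per
#'   category (applied to every age group) or a matrix with rows =
#'   [mobility_categories()] and columns = age groups. Non-negative; the work
#'   rate applies only to employed persons.
#' @param stringency_coef Named numeric vector, response of the log-rate per
#'   stringency point; must be <= 0 (tighter policy never increases trips).
#' @param seasonal_amplitude Amplitude of the seasonal log-rate sinusoid
#'   (dimensionless, on the log scale).
#' @param trip_distance_logmean,trip_distance_logsd Lognormal trip-distance
#'   parameters per category (km, log scale). Work trips ignore these for
#'   employed persons: they go to the person's fixed workplace.
#' @param trip_duration_mean Stay duration per category, hours.
#' @param noise_sd Standard deviation of the day-level log-rate noise.
#' @return An object of class `mob_latent_model`.
#' @export
latent_mobility_model <- function(base_rate,
                                  stringency_coef,
                                  seasonal_amplitude = 0,
                                  trip_distance_logmean = NULL,
                                  trip_distance_logsd = NULL,
                                  trip_duration_mean = NULL,
                                  noise_sd = 0) {
  cats <- mobility_categories()
  as_cat_vec <- function(x, what, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, 9), cats)
    if (!setequal(names(x), cats))
      abort(sprintf("`%s` must be named with exactly the 9 activity categories.", what))
    x[cats]
  }
  if (is.matrix(base_rate)) {
    if (!setequal(rownames(base_rate), cats))
      abort("`base_rate` matrix rows must be the 9 activity categories.")
    base_rate <- base_rate[cats, , drop = FALSE]
  } else {
    base_rate <- as_cat_vec(base_rate, "base_rate", NULL)
  }
  if (any(base_rate < 0)) abort("`base_rate` must be non-negative.")
  stringency_coef <- as_cat_vec(stringency_coef, "stringency_coef", NULL)
  if (any(stringency_coef > 0))
    abort("`stringency_coef` must be <= 0 for every category.")
  trip_distance_logmean <- as_cat_vec(trip_distance_logmean, "trip_distance_logmean",
                                      setNames(log(c(8, 2, 5, 2, 1.5, 3, 0.5, 1, 3)), cats))
  trip_distance_logsd <- as_cat_vec(trip_distance_logsd, "trip_distance_logsd",
                                    setNames(rep(0.6, 9), cats))
  if (any(trip_distance_logsd < 0)) abort("`trip_distance_logsd` must be >= 0.")
  trip_duration_mean <- as_cat_vec(trip_duration_mean, "trip_duration_mean",
                                   setNames(c(8, 1.5, 2.5, 1.2, 1, 1.5, 1, 1.5, 1.5), cats))
  if (any(trip_duration_mean <= 0)) abort("`trip_duration_mean` must be > 0.")
  stopifnot(noise_sd >= 0, seasonal_amplitude >= 0)
  structure(
    list(base_rate = base_rate, stringency_coef = stringency_coef,
         seasonal_amplitude = seasonal_amplitude,
         trip_distance_logmean = trip_distance_logmean,
         trip_distance_logsd = trip_distance_logsd,
         trip_duration_mean = trip_duration_mean, noise_sd = noise_sd),
    class = "mob_latent_model"
  )
}

#' Default latent mobility model
#'
#' Trip rates, stringency responses, distances and durations chosen to give a
#' plausible pre-pandemic activity mix (about 1.7 trips/day per person) with
#' discretionary activities (non-food shopping, meeting friends, boredom)
#' responding strongly to stringency and essential ones (food, medicine, pets)
#' weakly, so that a lockdown produces the familiar pattern of collapsing
#' retail/recreation mobility and near-constant grocery mobility.
#'
#' @param seasonal_amplitude Seasonal log-rate amplitude (default 0.15).
#' @param noise_sd Day-level log-rate noise (default 0.15).
#' @return A [latent_mobility_model()].
#' @export
default_latent_model <- function(seasonal_amplitude = 0.15, noise_sd = 0.15) {
  cats <- mobility_categories()
  base <- setNames(c(0.55, 0.25, 0.35, 0.08, 0.50, 0.30, 0.35, 0.20, 0.15), cats)
  ## age profile: younger persons do more sports/friends/boredom, older more
  ## medicine; work handled by the employment indicator
  age_mult <- cbind(
    "14-29" = setNames(c(1.0, 1.4, 1.4, 0.6, 0.9, 1.1, 0.8, 1.5, 1.0), cats),
    "30-59" = setNames(c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0), cats),
    "60-74" = setNames(c(1.0, 0.7, 0.8, 1.8, 1.1, 0.9, 1.3, 0.6, 1.0), cats)
  )
  latent_mobility_model(
    base_rate = base * age_mult,
    stringency_coef = setNames(
      c(-0.008, -0.012, -0.018, -0.002, -0.003, -0.020, -0.002, -0.015, -0.010),
      cats),
    seasonal_amplitude = seasonal_amplitude,
    noise_sd = noise_sd
  )
}

#' Simulate ground-truth stays
#'
#' For each person and day, draws per-category trip counts from the latent
#' Poisson log-linear model, gives every trip a destination (lognormal distance
#' from home at a uniform angle; employed persons' work trips go to their fixed
#' workplace), a duration, and a non-overlapping time slot within the day;
#' residual home stays tile the remainder so every day covers 00:00-24:00
#' exactly. One RNG substream per person makes the output independent of
#' processing order.
#'
#' @param persons Population tibble from [generate_population()].
#' @param model A [latent_mobility_model()].
#' @param stringency Tibble `date`, `stringency` covering all `dates`.
#' @param dates Vector of simulation `Date`s.
#' @param seed Integer seed.
#' @param day_cap_h Maximum total trip hours per day (default 22); a day whose
#'   drawn trip durations exceed it is rescaled so a home stay always remains.
#' @return A tibble of stays: `person_id`, `date`, `category` (one of the nine
#'   activities or `"home"`), `x_km`, `y_km`, `start_h`, `duration_h`,
#'   `dist_km` (one-way distance from home; 0 for home stays).
#' @export
simulate_stays <- function(persons, model, stringency, dates, seed,
                           day_cap_h = 22) {
  stopifnot(inherits(model, "mob_latent_model"), nrow(persons) >= 1)
  dates <- sort(unique(as.Date(dates)))
  n_days <- length(dates)
  s_map <- stringency$stringency[match(dates, stringency$date)]
  if (anyNA(s_map))
    abort("`stringency` does not cover every simulation date.")
  cats <- mobility_categories()
  doy <- as.integer(format(dates, "%j"))
  seas <- model$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365)
  day_part <- model$stringency_coef %o% s_map # 9 x n_days
  day_part <- sweep(day_part, 2, seas, `+`)

  rate_for <- function(age_group) {
    if (is.matrix(model$base_rate)) {
      if (!age_group %in% colnames(model$base_rate))
        abort(sprintf("No base rates for age group '%s'.", age_group))
      model$base_rate[, age_group]
    } else model$base_rate
  }

  seeds <- unit_stream_seed(seed, persons$person_id)
  out <- vector("list", nrow(persons))
  for (i in seq_len(nrow(persons))) {
    set.seed(seeds[i])
    out[[i]] <- simulate_person_stays(
      persons[i, ], model, rate_for(persons$age_group[i]),
      day_part, dates, n_days, cats, day_cap_h)
  }
  dplyr::bind_rows(out)
}

## One person's stays for all days; assumes the RNG is already seeded.
simulate_person_stays <- function(p, model, rates, day_part, dates, n_days,
                                  cats, day_cap_h) {
  if (!p$employed) rates["work"] <- 0
  eps <- rnorm(n_days, 0, model$noise_sd)
  ## lambda[c, d]; base_rate 0 gives log 0 = -Inf, hence lambda 0 and no trips
  loglam <- log(rates) + sweep(day_part, 2, eps, `+`)
  counts <- matrix(rpois(length(loglam), exp(loglam)), nrow = 9)

  cnt_vec <- as.vector(counts)                     # category fastest
  day_of <- rep(rep(seq_len(n_days), each = 9), cnt_vec)
  cat_of <- rep(rep(cats, n_days), cnt_vec)
  n_trips <- length(day_of)

  if (n_trips > 0) {
    dist <- rlnorm(n_trips, model$trip_distance_logmean[cat_of],
                   model$trip_distance_logsd[cat_of])
    theta <- runif(n_trips, 0, 2 * pi)
    x <- p$home_x_km + dist * cos(theta)
    y <- p$home_y_km + dist * sin(theta)
    if (p$employed) {
      w <- cat_of == "work"
      x[w] <- p$work_x_km
      y[w] <- p$work_y_km
      dist[w] <- sqrt((p$work_x_km - p$home_x_km)^2 +
                      (p$work_y_km - p$home_y_km)^2)
    }
    dur <- unname(model$trip_duration_mean[cat_of])
    day_tot <- rep(0, n_days)
    dt <- rowsum(dur, day_of)
    day_tot[as.integer(rownames(dt))] <- dt[, 1]
    over <- day_tot > day_cap_h
    if (any(over)) {
      f <- ifelse(over, day_cap_h / day_tot, 1)
      dur <- dur * f[day_of]
      day_tot <- pmin(day_tot, day_cap_h)
    }
  } else {
    dist <- x <- y <- dur <- numeric(0)
    day_tot <- rep(0, n_days)
  }

  ## schedule: each day is [gap, trip, gap, trip, ..., gap]; gap lengths are a
  ## random subdivision of the day's free time
  trips_per_day <- tabulate(day_of, n_days)
  gap_day <- rep(seq_len(n_days), trips_per_day + 1L)
  gap_raw <- runif(length(gap_day))
  gsum <- rowsum(gap_raw, gap_day)[, 1]
  free <- 24 - day_tot
  gap_dur <- unname(gap_raw / gsum[gap_day] * free[gap_day])

  k_trip <- if (n_trips > 0) stats::ave(rep(1, n_trips), day_of, FUN = seq_along) else numeric(0)
  k_gap <- stats::ave(rep(1, length(gap_day)), gap_day, FUN = seq_along)

  seg_day <- c(gap_day, day_of)
  seg_pos <- c(2 * k_gap - 1, 2 * k_trip)
  seg_cat <- c(rep("home", length(gap_day)), cat_of)
  seg_dur <- c(gap_dur, dur)
  seg_x <- c(rep(p$home_x_km, length(gap_day)), x)
  seg_y <- c(rep(p$home_y_km, length(gap_day)), y)
  seg_dist <- c(rep(0, length(gap_day)), dist)

  ord <- order(seg_day, seg_pos)
  seg_day <- seg_day[ord]
  seg_dur <- unname(seg_dur[ord])
  start <- unname(stats::ave(seg_dur, seg_day, FUN = cumsum) - seg_dur)

  tibble::tibble(
    person_id = p$person_id, date = dates[seg_day],
    category = seg_cat[ord], x_km = seg_x[ord], y_km = seg_y[ord],
    start_h = start, duration_h = seg_dur, dist_km = seg_dist[ord]
  )
}

#' Ground-truth weekly mobility
#'
#' Weekly per-person population mean of a mobility measure computed directly
#' from the ground-truth stays; the recovery target the observation channels
#' are judged against in simulation studies.
#'
#' @param stays Tibble from [simulate_stays()].
#' @param measure `"trip_count"` (non-home stays per person-week) or
#'   `"total_distance"` (round-trip km per person-week: each trip contributes
#'   twice its one-way distance from home).
#' @return A tibble `week` (ISO Monday), `value`.
#' @export
true_weekly_mobility <- function(stays, measure = c("trip_count", "total_distance")) {
  measure <- rlang::arg_match(measure)
  n_persons <- dplyr::n_distinct(stays$person_id)
  weeks <- sort(unique(iso_week_start(stays$date)))
  trips <- dplyr::filter(stays, .data$category != "home")
  agg <- trips |>
    dplyr::mutate(week = iso_week_start(.data$date)) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(
      value = if (measure == "trip_count") dplyr::n() / n_persons
              else sum(2 * .data$dist_km) / n_persons,
      .groups = "drop")
  tibble::tibble(week = weeks) |>
    dplyr::left_join(agg, by = "week") |>
    dplyr::mutate(value = tidyr::replace_na(.data$value, 0))
}

#' Write / read stays CSV
#'
#' One row per stay with an ISO-8601 start timestamp:
#' `person_id,category,x_km,y_km,start_iso8601,duration_h`.
#'
#' @param stays Stays tibble.
#' @param path File path.
#' @return `write_stays_csv()` returns `path` invisibly; `read_stays_csv()`
#'   returns a stays tibble (without `dist_km`, which is ground-truth only).
#' @export
write_stays_csv <- function(stays, path) {
  hh <- floor(stays$start_h)
  mm <- floor((stays$start_h - hh) * 60)
  ss <- round(((stays$start_h - hh) * 60 - mm) * 60, 3)
  out <- tibble::tibble(
    person_id = stays$person_id, category = stays$category,
    x_km = stays$x_km, y_km = stays$y_km,
    start_iso8601 = sprintf("%sT%02d:%02d:%06.3f", format(stays$date), hh, mm, ss),
    duration_h = stays$duration_h)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_stays_csv
#' @export
read_stays_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(start_iso8601 = readr::col_character()))
  ts <- as.POSIXct(x$start_iso8601, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  tibble::tibble(
    person_id = x$person_id, date = as.Date(ts),
    category = x$category, x_km = x$x_km, y_km = x$y_km,
    start_h = as.numeric(ts - as.POSIXct(paste0(as.Date(ts), " 00:00:00"), tz = "UTC"),
                         units = "hours"),
    duration_h = x$duration_h)
}
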