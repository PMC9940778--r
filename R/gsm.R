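#' Tower grid for GSM observation
#'
#' A regular square grid of base-station locations; localization events are
#' snapped to the nearest grid node, emulating the positional coarseness of
#' mobile-network data.
#'
#' @param spacing_km Grid spacing (> 0).
#' @param origin Numeric length-2 offset of the grid (km).
#' @return An object of class `mob_tower_grid`.
#' @export
tower_grid <- function(spacing_km = 1, origin = c(0, 0)) {
  if (!is.numeric(spacing_km) || spacing_km <= 0)
    abort("`spacing_km` must be > 0.")
  structure(list(spacing_km = spacing_km, origin = as.numeric(origin)),
            class = "mob_tower_grid")
}

snap_to_grid <- function(x, y, grid) {
  s <- grid$spacing_km
  list(x = round((x - grid$origin[1]) / s) * s + grid$origin[1],
       y = round((y - grid$origin[2]) / s) * s + grid$origin[2])
}

#' Observe stays through the GSM network
#'
#' Every covered person becomes one device. Within each stay, communication
#' events occur as a Poisson process at `event_rate_per_hour`; each event is
#' located at the tower (grid node) nearest to the stay's true location. The
#' dwell weight of an event is the time until the device's next event that day
#' (the last event of a day keeps its weight until midnight): a device "stays"
#' at a tower until it is re-observed.
#'
#' @param stays Stays tibble from [simulate_stays()].
#' @param grid A [tower_grid()].
#' @param event_rate_per_hour Poisson event rate (> 0).
#' @param coverage_prob Probability a person is a customer of the observed
#'   network, in (0, 1].
#' @param seed Integer seed.
#' @return Tibble of localization events: `device_id`, `date`, `time_h`,
#'   `x_km`, `y_km` (tower coordinates), `dwell_h`, ordered by device and time.
#' @export
observe_gsm_events <- function(stays, grid, event_rate_per_hour = 0.35,
                               coverage_prob = 1, seed = 1) {
  stopifnot(inherits(grid, "mob_tower_grid"))
  if (event_rate_per_hour <= 0) abort("`event_rate_per_hour` must be > 0.")
  if (coverage_prob <= 0 || coverage_prob > 1)
    abort("`coverage_prob` must be in (0, 1].")
  set.seed(as.integer(seed))
  ids <- sort(unique(stays$person_id))
  covered <- ids[runif(length(ids)) <= coverage_prob]
  st <- dplyr::filter(stays, .data$person_id %in% covered)
  if (nrow(st) == 0) {
    return(tibble::tibble(device_id = integer(), date = as.Date(character()),
                          time_h = numeric(), x_km = numeric(), y_km = numeric(),
                          dwell_h = numeric()))
  }
  n_ev <- rpois(nrow(st), event_rate_per_hour * st$duration_h)
  ix <- rep(seq_len(nrow(st)), n_ev)
  time_h <- st$start_h[ix] + runif(length(ix)) * st$duration_h[ix]
  tw <- snap_to_grid(st$x_km[ix], st$y_km[ix], grid)
  ev <- tibble::tibble(
    device_id = st$person_id[ix], date = st$date[ix], time_h = time_h,
    x_km = tw$x, y_km = tw$y)
  ev <- dplyr::arrange(ev, .data$device_id, .data$date, .data$time_h)
  nxt <- dplyr::lead(ev$time_h)
  same <- dplyr::lead(ev$device_id) == ev$device_id &
    dplyr::lead(ev$date) == ev$date
  ev$dwell_h <- ifelse(!is.na(same) & same, nxt - ev$time_h, 24 - ev$time_h)
  ev
}

#' Radius of gyration of one event set
#'
#' Time-weighted root-mean-square distance between each localization and the
#' time-weighted center of gravity (the coordinate-wise weighted average):
#' `ROG = sqrt( sum(w_i * d(x_i, c)^2) / sum(w_i) )` with
#' `c = sum(w_i * x_i) / sum(w_i)`.
#'
#' @param x,y Coordinates (planar km, or lon/lat in haversine mode).
#' @param w Dwell weights (> 0), recycled if length 1.
#' @param distance `"euclidean"` (planar, exact) or `"haversine"` (lon/lat in
#'   degrees, great-circle km; requires the geosphere package).
#' @return Radius of gyration in km (single non-negative number); `NA` for an
#'   empty event set (never 0).
#' @export
#' @examples
#' radius_of_gyration(c(0, 4), c(0, 0), c(1, 1)) # 2
radius_of_gyration <- function(x, y, w = 1, distance = c("euclidean", "haversine")) {
  distance <- rlang::arg_match(distance)
  if (length(x) == 0) return(NA_real_)
  w <- rep_len(w, length(x))
  if (any(w <= 0)) abort("Dwell weights must be > 0.")
  if (all(x == x[1]) && all(y == y[1])) return(0) # one tower: exactly zero
  W <- sum(w)
  cx <- sum(w * x) / W
  cy <- sum(w * y) / W
  if (distance == "euclidean") {
    d2 <- (x - cx)^2 + (y - cy)^2
  } else {
    if (!requireNamespace("geosphere", quietly = TRUE))
      abort("Haversine mode requires the geosphere package.")
    d2 <- (geosphere::distHaversine(cbind(x, y), c(cx, cy)) / 1000)^2
  }
  sqrt(sum(w * d2) / W)
}

#' Device-day radius of gyration
#'
#' Computes the time-weighted ROG per device and date from a localization
#' event table.
#'
#' @param events Tibble from [observe_gsm_events()] (columns `device_id`,
#'   `date`, `x_km`, `y_km`, `dwell_h`).
#' @param distance Passed to [radius_of_gyration()].
#' @return Tibble `device_id`, `date`, `rog_km`, `n_events`.
#' @export
device_day_rog <- function(events, distance = c("euclidean", "haversine")) {
  distance <- rlang::arg_match(distance)
  if (nrow(events) == 0)
    return(tibble::tibble(device_id = integer(), date = as.Date(character()),
                          rog_km = numeric(), n_events = integer()))
  if (distance == "haversine") {
    return(events |>
      dplyr::group_by(.data$device_id, .data$date) |>
      dplyr::summarise(
        rog_km = radius_of_gyration(.data$x_km, .data$y_km, .data$dwell_h,
                                    distance = "haversine"),
        n_events = dplyr::n(), .groups = "drop"))
  }
  ## vectorized grouped two-pass formula (euclidean): weighted center per
  ## device-day, then weighted mean of squared distances
  key <- paste(events$device_id, events$date)
  gi <- match(key, unique(key))
  w <- events$dwell_h
  if (any(w <= 0)) abort("Dwell weights must be > 0.")
  W <- rowsum(w, gi)[, 1]
  cx <- rowsum(w * events$x_km, gi)[, 1] / W
  cy <- rowsum(w * events$y_km, gi)[, 1] / W
  d2 <- (events$x_km - cx[gi])^2 + (events$y_km - cy[gi])^2
  rog <- sqrt(pmax(rowsum(w * d2, gi)[, 1] / W, 0))
  ## single-tower device-days are exactly zero (no floating-point residue)
  ref <- match(gi, gi)
  moved <- events$x_km != events$x_km[ref] | events$y_km != events$y_km[ref]
  rog[rowsum(as.numeric(moved), gi)[, 1] == 0] <- 0
  first <- !duplicated(gi)
  tibble::tibble(device_id = events$device_id[first], date = events$date[first],
                 rog_km = unname(rog), n_events = tabulate(gi))
}

#' Daily median ROG by group
#'
#' The ROG distribution over devices is heavily right-skewed, so daily
#' aggregates use the median across devices. An even device count takes the
#' mean of the two central order statistics; an empty group-date yields `NA`.
#'
#' @param rog Tibble from [device_day_rog()], optionally carrying grouping
#'   columns (e.g. after joining device demographics).
#' @param by Character vector of grouping column names (default none:
#'   population-level medians).
#' @return Tibble with `by` columns, `date`, `median_rog_km`, `n_devices`.
#' @export
daily_median_rog <- function(rog, by = character()) {
  stopifnot(all(by %in% names(rog)))
  rog |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "date")))) |>
    dplyr::summarise(
      median_rog_km = stats::median(.data$rog_km, na.rm = TRUE),
      n_devices = sum(!is.na(.data$rog_km)), .groups = "drop") |>
    dplyr::mutate(median_rog_km = ifelse(.data$n_devices == 0, NA_real_,
                                         .data$median_rog_km))
}

#' Share of device-days with ROG above a threshold
#'
#' The alternative population-mobility measure: the proportion of devices whose
#' daily ROG strictly exceeds `threshold_km` (default 0.5 km, i.e. "more than
#' 500 meters").
#'
#' @param rog Tibble from [device_day_rog()].
#' @param threshold_km Strict threshold (> 0).
#' @param by Extra grouping columns.
#' @return Tibble with `by` columns, `date`, `share_above`, `n_devices`.
#' @export
share_rog_above <- function(rog, threshold_km = 0.5, by = character()) {
  if (threshold_km <= 0) abort("`threshold_km` must be > 0.")
  rog |>
    dplyr::filter(!is.na(.data$rog_km)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "date")))) |>
    dplyr::summarise(share_above = mean(.data$rog_km > threshold_km),
                     n_devices = dplyr::n(), .groups = "drop")
}

#' Write / read localization-event CSV
#'
#' Columns `device_id,timestamp_iso8601,x_km,y_km,dwell_h` (planar mode) or
#' `device_id,timestamp_iso8601,lon,lat,dwell_h` with `mode = "lonlat"`.
#'
#' @param events Event tibble.
#' @param path File path.
#' @param mode `"planar"` or `"lonlat"` (column naming only).
#' @return `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path, mode = c("planar", "lonlat")) {
  mode <- rlang::arg_match(mode)
  hh <- floor(events$time_h)
  mm <- floor((events$time_h - hh) * 60)
  ss <- round(((events$time_h - hh) * 60 - mm) * 60, 3)
  out <- tibble::tibble(
    device_id = events$device_id,
    timestamp_iso8601 = sprintf("%sT%02d:%02d:%06.3f", format(events$date), hh, mm, ss),
    x = events$x_km, y = events$y_km, dwell_h = events$dwell_h)
  names(out)[3:4] <- if (mode == "planar") c("x_km", "y_km") else c("lon", "lat")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, mode = c("planar", "lonlat")) {
  mode <- rlang::arg_match(mode)
  x <- readr::read_csv(path, show_col_types = FALSE)
  coord <- if (mode == "planar") c("x_km", "y_km") else c("lon", "lat")
  need <- c("device_id", "timestamp_iso8601", coord, "dwell_h")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort(paste0("Event CSV is missing column(s): ", paste(miss, collapse = ", ")))
  ts <- as.POSIXct(x$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  tibble::tibble(
    device_id = x$device_id, date = as.Date(ts),
    time_h = as.numeric(ts - as.POSIXct(paste0(as.Date(ts), " 00:00:00"), tz = "UTC"),
                        units = "hours"),
    x_km = x[[coord[1]]], y_km = x[[coord[2]]], dwell_h = x$dwell_h)
}
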