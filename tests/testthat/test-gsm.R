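test_that("ROG matches hand-derived analytic cases", {
  # single localization: no spread
  expect_identical(radius_of_gyration(3, 5, 2.5), 0)
  # two equal-weight points 4 km apart: RMS distance from midpoint
  expect_equal(radius_of_gyration(c(0, 4), c(0, 0), c(1, 1)), 2,
               tolerance = 1e-12)
  # weights 3:1 at 4 km: center (1, 0), sqrt((3*1 + 1*9)/4) = sqrt(3)
  expect_equal(radius_of_gyration(c(0, 4), c(0, 0), c(3, 1)), sqrt(3),
               tolerance = 1e-12)
  # empty event set is undefined, never 0
  expect_true(is.na(radius_of_gyration(numeric(0), numeric(0), numeric(0))))
})

test_that("ROG is translation-, rotation- and scale-consistent", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:15, 1)
    x <- rnorm(n, sd = 5); y <- rnorm(n, sd = 5); w <- runif(n, 0.1, 3)
    r0 <- radius_of_gyration(x, y, w)
    expect_equal(radius_of_gyration(x + 100, y - 42, w), r0, tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    xr <- x * cos(th) - y * sin(th)
    yr <- x * sin(th) + y * cos(th)
    expect_equal(radius_of_gyration(xr, yr, w), r0, tolerance = 1e-9)
    k <- runif(1, 0.1, 10)
    expect_equal(radius_of_gyration(k * x, k * y, w), k * r0, tolerance = 1e-9)
  }
})

test_that("device-day ROG equals the two-pass oracle and is 0 iff one tower", {
  set.seed(22)
  ev <- purrr::map_dfr(1:200, function(g) {
    n <- sample(1:12, 1)
    one_tower <- runif(1) < 0.3
    tibble::tibble(
      device_id = g %% 37, date = as.Date("2020-04-01") + g %/% 37,
      time_h = sort(runif(n, 0, 24)),
      x_km = if (one_tower) rep(round(rnorm(1)), n) else round(rnorm(n, sd = 3)),
      y_km = if (one_tower) rep(round(rnorm(1)), n) else round(rnorm(n, sd = 3)),
      dwell_h = runif(n, 0.01, 5))
  })
  got <- device_day_rog(ev)
  oracle <- ev |>
    dplyr::group_by(device_id, date) |>
    dplyr::summarise(rog_km = rog_oracle(x_km, y_km, dwell_h), .groups = "drop")
  j <- dplyr::left_join(got, oracle, by = c("device_id", "date"))
  expect_lt(max(abs(j$rog_km.x - j$rog_km.y)), 1e-9)

  one_tower <- ev |>
    dplyr::group_by(device_id, date) |>
    dplyr::summarise(single = dplyr::n_distinct(paste(x_km, y_km)) == 1,
                     .groups = "drop")
  j2 <- dplyr::left_join(got, one_tower, by = c("device_id", "date"))
  expect_equal(j2$rog_km == 0, j2$single)
})

test_that("events snap to the nearest tower and dwell weights telescope", {
  pop <- tiny_population(1)
  pop$home_x_km <- 0.4
  pop$home_y_km <- 0
  dates <- as.Date("2020-03-02")
  st <- simulate_stays(pop, flat_model(base = 0), const_stringency(dates),
                       dates, seed = 1)
  ev <- observe_gsm_events(st, tower_grid(1), event_rate_per_hour = 1,
                           coverage_prob = 1, seed = 2)
  # stay at (0.4, 0) with unit grid: nearest node is the origin
  expect_true(all(ev$x_km == 0 & ev$y_km == 0))
  # forward dwell weights telescope to (24 - time of first event)
  expect_equal(sum(ev$dwell_h), 24 - min(ev$time_h), tolerance = 1e-9)
  expect_true(all(ev$dwell_h > 0))

  # multi-person, multi-day: telescoping holds per device-day
  pop2 <- tiny_population(5)
  dates2 <- as.Date("2020-03-02") + 0:4
  st2 <- simulate_stays(pop2, flat_model(base = 0.6), const_stringency(dates2),
                        dates2, seed = 3)
  ev2 <- observe_gsm_events(st2, tower_grid(1), 0.8, 1, seed = 4)
  sums <- ev2 |>
    dplyr::group_by(device_id, date) |>
    dplyr::summarise(total = sum(dwell_h), first = min(time_h), .groups = "drop")
  expect_equal(sums$total, 24 - sums$first, tolerance = 1e-9)
})

test_that("haversine mode measures great-circle spread for lon/lat input", {
  skip_if_not_installed("geosphere")
  # two equal-weight points one degree of latitude apart: ROG is half the
  # great-circle distance, by symmetry
  d_m <- geosphere::distHaversine(c(16.37, 48.0), c(16.37, 49.0))
  expect_equal(radius_of_gyration(c(16.37, 16.37), c(48, 49), c(1, 1),
                                  distance = "haversine"),
               d_m / 2000, tolerance = 1e-6)
  ev <- tibble::tibble(device_id = 1L, date = as.Date("2020-04-01"),
                       x_km = c(16.37, 16.37), y_km = c(48, 49),
                       dwell_h = c(1, 1))
  expect_equal(device_day_rog(ev, distance = "haversine")$rog_km,
               d_m / 2000, tolerance = 1e-6)
})

test_that("an all-day home stay yields a single tower and zero ROG", {
  pop <- tiny_population(2)
  dates <- as.Date("2020-03-02") + 0:2
  st <- simulate_stays(pop, flat_model(base = 0), const_stringency(dates),
                       dates, seed = 5)
  ev <- observe_gsm_events(st, tower_grid(1), 0.5, 1, seed = 6)
  rog <- device_day_rog(ev)
  expect_true(all(rog$rog_km == 0))
})

test_that("daily median ROG uses the even-count convention and is robust", {
  rg <- tibble::tibble(device_id = 1:3, date = as.Date("2020-04-01"),
                       rog_km = c(1, 2, 100), n_events = 5L)
  expect_equal(daily_median_rog(rg)$median_rog_km, 2)
  rg2 <- rg[1:2, ]
  rg2$rog_km <- c(1, 3)
  expect_equal(daily_median_rog(rg2)$median_rog_km, 2)

  # an injected outlier moves the median at most to the adjacent order statistic
  set.seed(30)
  base <- sort(runif(9, 0, 10))
  rg3 <- tibble::tibble(device_id = 1:9, date = as.Date("2020-04-01"),
                        rog_km = base, n_events = 1L)
  m0 <- daily_median_rog(rg3)$median_rog_km
  rg4 <- dplyr::bind_rows(rg3, tibble::tibble(
    device_id = 10L, date = as.Date("2020-04-01"), rog_km = 1e6, n_events = 1L))
  m1 <- daily_median_rog(rg4)$median_rog_km
  gap <- base[which(base == m0) + 1] - m0
  expect_lte(abs(m1 - m0), gap + 1e-12)
})

test_that("share of ROG above threshold uses a strict inequality", {
  rg <- tibble::tibble(device_id = 1:3, date = as.Date("2020-04-01"),
                       rog_km = c(0.2, 0.6, 1.0), n_events = 1L)
  expect_equal(share_rog_above(rg, 0.5)$share_above, 2 / 3)
  rg$rog_km <- c(0.1, 0.2, 0.3)
  expect_equal(share_rog_above(rg, 0.5)$share_above, 0)
  rg$rog_km <- c(0.5, 0.5, 0.7) # exactly at the threshold: not counted
  expect_equal(share_rog_above(rg, 0.5)$share_above, 1 / 3)
  expect_error(share_rog_above(rg, 0), "> 0")
})

test_that("event CSV round trip preserves values and flags missing columns", {
  pop <- tiny_population(3)
  dates <- as.Date("2020-03-02") + 0:1
  st <- simulate_stays(pop, flat_model(base = 0.5), const_stringency(dates),
                       dates, seed = 7)
  ev <- observe_gsm_events(st, tower_grid(1), 0.7, 1, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, path)
  back <- read_events_csv(path)
  expect_equal(back$device_id, ev$device_id)
  expect_equal(back$x_km, ev$x_km)
  expect_equal(back$dwell_h, ev$dwell_h)
  expect_equal(back$time_h, ev$time_h, tolerance = 1e-3)

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(device_id = 1, x_km = 0), bad)
  expect_error(read_events_csv(bad), "missing column")
})

test_that("coverage subsampling keeps a person-level panel of devices", {
  pop <- tiny_population(30)
  dates <- as.Date("2020-03-02") + 0:3
  st <- simulate_stays(pop, flat_model(base = 0.4), const_stringency(dates),
                       dates, seed = 9)
  ev <- observe_gsm_events(st, tower_grid(1), 0.5, coverage_prob = 0.5, seed = 10)
  expect_lt(dplyr::n_distinct(ev$device_id), 30)
  expect_true(all(ev$device_id %in% pop$person_id))
  expect_error(observe_gsm_events(st, tower_grid(1), 0.5, 0, seed = 1), "\\(0, 1\\]")
})
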