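test_that("wave schedule follows the weekly/bi-weekly/four-weekly cadence", {
  sch <- wave_schedule()
  expect_equal(nrow(sch), 22L)
  expect_equal(sch$start_date[1], as.Date("2020-03-23"))
  expect_equal(sch$end_date[1], as.Date("2020-03-29"))
  gaps <- as.integer(diff(sch$start_date)) / 7
  expect_equal(gaps[1:9], rep(1, 9))       # waves 1-10 weekly
  expect_equal(gaps[10:13], rep(2, 4))     # waves 11-14 bi-weekly
  expect_equal(gaps[14:21], rep(4, 8))     # waves 15-22 four-weekly
  expect_error(wave_schedule(as.Date("2020-03-24")), "Monday")
})

test_that("zero-noise responses reproduce the day-count threshold map exactly", {
  # 3 persons, first field week; craft stays with known active-day counts
  pop <- tiny_population(3)
  sch <- wave_schedule(n_waves = 1)
  dates <- seq(sch$start_date[1], sch$end_date[1], by = "day")
  home <- simulate_stays(pop, flat_model(base = 0), const_stringency(dates),
                         dates, seed = 1)
  mk_trip <- function(pid, cat, days) tibble::tibble(
    person_id = pid, date = dates[days], category = cat, x_km = 1, y_km = 1,
    start_h = 10, duration_h = 1, dist_km = 1)
  st <- dplyr::bind_rows(
    home,
    mk_trip(pop$person_id[1], "food", 1:3),     # 3 active days -> code 2
    mk_trip(pop$person_id[2], "work", 1:7),     # daily -> code 4
    mk_trip(pop$person_id[2], "sports", 1),     # one day -> code 1
    mk_trip(pop$person_id[3], "pets", 1:5))     # 5 days -> code 3
  rm0 <- response_model(recall_noise_sd = 0, item_nonresponse_prob = 0,
                        attrition_prob = 0)
  resp <- administer_survey(pop, st, sch, rm0, seed = 2)
  r1 <- resp[resp$respondent_id == pop$person_id[1], ]
  expect_equal(r1$item_food, 2L)
  expect_equal(sum(r1[paste0("item_", mobility_categories())]), 2)
  r2 <- resp[resp$respondent_id == pop$person_id[2], ]
  expect_equal(r2$item_work, 4L)
  expect_equal(r2$item_sports, 1L)
  r3 <- resp[resp$respondent_id == pop$person_id[3], ]
  expect_equal(r3$item_pets, 3L)
  # stay-home: person 2 left home on all 7 days -> 0 home-only days -> code 0
  expect_equal(r2$item_stayhome, 0L)
  # person 1: 4 home-only days -> code 3
  expect_equal(r1$item_stayhome, 3L)
})

test_that("the count-to-code thresholds map 0..7 days to 0,1,2,2,3,3,3,4", {
  # via a single person with k active days, zero noise
  pop <- tiny_population(1)
  sch <- wave_schedule(n_waves = 1)
  dates <- seq(sch$start_date[1], sch$end_date[1], by = "day")
  home <- simulate_stays(pop, flat_model(base = 0), const_stringency(dates),
                         dates, seed = 1)
  rm0 <- response_model(recall_noise_sd = 0, item_nonresponse_prob = 0,
                        attrition_prob = 0)
  codes <- sapply(0:7, function(k) {
    st <- if (k == 0) home else dplyr::bind_rows(home, tibble::tibble(
      person_id = pop$person_id[1], date = dates[seq_len(k)], category = "food",
      x_km = 1, y_km = 1, start_h = 10, duration_h = 1, dist_km = 1))
    administer_survey(pop, st, sch, rm0, seed = 3)$item_food
  })
  expect_equal(codes, c(0L, 1L, 2L, 2L, 3L, 3L, 3L, 4L))
})

test_that("sample filters drop 75+ and incomplete responses, with counts", {
  resp <- tibble::tibble(
    respondent_id = 1:4, wave = 1L,
    age_group = c("30-59", "75+", "14-29", "60-74"),
    gender = "female", region = "east")
  for (cc in paste0("item_", mobility_categories())) resp[[cc]] <- 2L
  resp$item_stayhome <- 1L
  resp$item_sports[3] <- NA_integer_
  out <- filter_sample(resp, quiet = TRUE)
  expect_equal(out$respondent_id, c(1L, 4L))
  expect_equal(unname(attr(out, "filter_counts")),
               c(1L, 1L, 2L), ignore_attr = TRUE)
})

test_that("mobility index sums the nine items with typed subindices", {
  resp <- tibble::tibble(respondent_id = 1:3, wave = 1L, age_group = "30-59",
                         gender = "male", region = "east")
  for (cc in paste0("item_", mobility_categories())) resp[[cc]] <- 0L
  resp[2, paste0("item_", mobility_categories())] <- as.list(rep(4L, 9))
  resp$item_work[3] <- 2L
  resp$item_food[3] <- 3L
  resp$item_medicine[3] <- 1L
  idx <- mobility_index(resp)
  expect_equal(idx$index, c(0L, 36L, 6L))
  expect_equal(idx$sub_food_medicine, c(0L, 8L, 4L))
  expect_equal(idx$sub_work, c(0L, 4L, 2L))
  expect_equal(idx$sub_nonfood, c(0L, 4L, 0L))
})

test_that("index stays within bounds on fuzzed stays and response models", {
  pop <- tiny_population(15, employment = 0.5)
  sch <- wave_schedule(n_waves = 3)
  dates <- seq(min(sch$start_date), max(sch$end_date), by = "day")
  for (s in 1:4) {
    st <- simulate_stays(pop, flat_model(base = runif(1, 0, 2), noise_sd = 0.3),
                         const_stringency(dates, 30), dates, seed = s)
    rm <- response_model(recall_noise_sd = runif(1, 0, 3),
                         desirability_shift = sample(0:2, 1),
                         item_nonresponse_prob = 0.1, attrition_prob = 0.1)
    resp <- administer_survey(pop, st, sch, rm, seed = s + 100)
    items <- as.matrix(resp[paste0("item_", mobility_categories())])
    expect_true(all(items %in% c(0:4, NA)))
    idx <- mobility_index(filter_sample(resp, quiet = TRUE))
    expect_true(all(idx$index >= 0 & idx$index <= 36))
    expect_true(all(idx$sub_food_medicine >= 0 & idx$sub_food_medicine <= 8))
    expect_true(all(idx$sub_nonfood >= 0 & idx$sub_nonfood <= 4))
  }
})

test_that("a larger desirability shift weakly lowers every wave aggregate", {
  pop <- tiny_population(40)
  sch <- wave_schedule(n_waves = 4)
  dates <- seq(min(sch$start_date), max(sch$end_date), by = "day")
  st <- simulate_stays(pop, flat_model(base = 0.8), const_stringency(dates, 10),
                       dates, seed = 11)
  agg <- function(shift) {
    rm <- response_model(recall_noise_sd = 0, desirability_shift = shift,
                         item_nonresponse_prob = 0, attrition_prob = 0)
    resp <- administer_survey(pop, st, sch, rm, seed = 12)
    idx <- mobility_index(filter_sample(resp, quiet = TRUE))
    tapply(idx$index, idx$wave, mean)
  }
  expect_true(all(agg(1) <= agg(0)))
})

test_that("stay-home aggregate is a weighted wave mean", {
  resp <- tibble::tibble(respondent_id = 1:2, wave = 1L,
                         item_stayhome = c(0L, 4L))
  expect_equal(stay_home_measure(resp)$value, 2)
  w <- tibble::tibble(respondent_id = 1:2, wave = 1L, weight = c(3, 1))
  expect_equal(stay_home_measure(resp, w)$value, 1)
  resp4 <- dplyr::mutate(resp, item_stayhome = 4L)
  expect_equal(stay_home_measure(resp4)$value, 4)
  # empty wave: no rows, not a zero
  expect_equal(nrow(stay_home_measure(resp[0, ])), 0L)
})

test_that("attrition with refreshment keeps wave sizes approximately stable", {
  pop <- tiny_population(100)
  sch <- wave_schedule(n_waves = 6)
  dates <- seq(min(sch$start_date), max(sch$end_date), by = "day")
  st <- simulate_stays(pop, flat_model(base = 0.3), const_stringency(dates),
                       dates, seed = 13)
  rm <- response_model(recall_noise_sd = 0.5, attrition_prob = 0.15)
  resp <- administer_survey(pop, st, sch, rm, seed = 14, panel_size = 50)
  sizes <- table(resp$wave)
  expect_true(all(sizes == 50)) # refreshment pool is large enough here
  expect_gt(dplyr::n_distinct(resp$respondent_id), 50)
  # panelists keep stable ids across waves
  expect_true(all(resp$respondent_id %in% pop$person_id))
})

test_that("responses CSV round trip preserves codes and missing cells", {
  resp <- tibble::tibble(respondent_id = 1:3, wave = 1L, age_group = "30-59",
                         gender = "female", region = "east")
  for (cc in paste0("item_", mobility_categories())) resp[[cc]] <- c(1L, NA, 4L)
  resp$item_stayhome <- c(NA, 2L, 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses_csv(resp, path)
  back <- read_responses_csv(path)
  expect_equal(back$item_work, resp$item_work)
  expect_equal(back$item_stayhome, resp$item_stayhome)
  expect_true(grepl(",,", readLines(path)[3])) # blank = missing
})
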