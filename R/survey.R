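#' Panel wave schedule
#'
#' The 22-wave fielding calendar: waves 1-10 weekly, 11-14 bi-weekly, 15-22
#' every four weeks, each wave covering one Monday-Sunday field week starting
#' from the baseline week (default 2020-03-23).
#'
#' @param start Start date of wave 1 (a Monday).
#' @param n_waves Number of waves (default 22).
#' @return Tibble `wave`, `start_date`, `end_date`.
#' @export
#' @examples
#' wave_schedule()
wave_schedule <- function(start = as.Date("2020-03-23"), n_waves = 22) {
  start <- as.Date(start)
  if (as.integer(format(start, "%u")) != 1)
    abort("`start` must be a Monday (field weeks are ISO weeks).")
  offsets <- c(0:9, c(11, 13, 15, 17), seq(21, by = 4, length.out = 8))
  if (n_waves < 1 || n_waves > length(offsets))
    abort(sprintf("`n_waves` must be between 1 and %d.", length(offsets)))
  offsets <- offsets[seq_len(n_waves)]
  tibble::tibble(wave = seq_len(n_waves),
                 start_date = start + offsets * 7L,
                 end_date = start + offsets * 7L + 6L)
}

#' Survey response model
#'
#' Measurement-error parameters for the self-report channel. The true quantity
#' per item is the number of days (0-7) in the field week with at least one
#' trip in that category; it is perturbed by Gaussian recall noise, mapped to
#' the 5-point frequency code via the thresholds 0 days -> 0 ("never"),
#' 1 day -> 1, 2-3 days -> 2, 4-6 days -> 3, 7 days -> 4 ("daily"), shifted
#' down by a social-desirability bias, and clamped to 0-4.
#'
#' @param recall_noise_sd SD of the Gaussian noise added to the true day count
#'   before rounding (0 = perfect recall).
#' @param desirability_shift Downward shift of the item code (code units);
#'   rounded to the nearest integer before subtraction.
#' @param desirability_stringency_slope Additional shift per stringency point
#'   of the field week's mean stringency divided by 100 (so a slope of 1 adds
#'   up to one code step under full stringency).
#' @param item_nonresponse_prob Probability each item is individually missing.
#' @param attrition_prob Per-wave probability a panelist drops out after
#'   responding.
#' @return An object of class `mob_response_model`.
#' @export
response_model <- function(recall_noise_sd = 0.7, desirability_shift = 0,
                           desirability_stringency_slope = 0,
                           item_nonresponse_prob = 0.01, attrition_prob = 0.04) {
  stopifnot(recall_noise_sd >= 0, desirability_shift >= 0,
            desirability_stringency_slope >= 0,
            item_nonresponse_prob >= 0, item_nonresponse_prob <= 1,
            attrition_prob >= 0, attrition_prob < 1)
  structure(list(recall_noise_sd = recall_noise_sd,
                 desirability_shift = desirability_shift,
                 desirability_stringency_slope = desirability_stringency_slope,
                 item_nonresponse_prob = item_nonresponse_prob,
                 attrition_prob = attrition_prob),
            class = "mob_response_model")
}

## days-active (0-7) -> 5-point frequency code
count_to_code <- function(n_days) {
  n_days <- pmin(7, pmax(0, n_days))
  c(0L, 1L, 2L, 2L, 3L, 3L, 3L, 4L)[as.integer(n_days) + 1L]
}

survey_item_cols <- function() paste0("item_", mobility_categories())

#' Administer the panel survey
#'
#' Fields each wave to the current panel, computing every item's true active-day
#' count from the ground-truth stays and passing it through the response model
#' ([response_model()]). Panelists drop out between waves with the attrition
#' probability and are replaced by previously unsampled persons so the wave
#' size stays approximately constant while the panel remains a panel
#' (respondent IDs are stable across waves). The stay-home item reports the
#' number of days with no trip at all, on the same 5-point code.
#'
#' @param persons Population tibble; the first `panel_size` sampled persons
#'   form the initial panel.
#' @param stays Ground-truth stays covering all field weeks.
#' @param schedule Tibble from [wave_schedule()].
#' @param model A [response_model()].
#' @param seed Integer seed.
#' @param panel_size Initial panel size (default: all persons; replacement then
#'   impossible, so attrition shrinks waves).
#' @param stringency Optional stringency series (needed when
#'   `desirability_stringency_slope > 0`).
#' @return Tibble with one row per respondent x wave: `respondent_id`, `wave`,
#'   demographics, the nine `item_*` codes (0-4 or `NA`), `item_stayhome`.
#' @export
administer_survey <- function(persons, stays, schedule, model, seed,
                              panel_size = nrow(persons), stringency = NULL) {
  stopifnot(inherits(model, "mob_response_model"))
  if (max(schedule$end_date) > max(stays$date) ||
      min(schedule$start_date) < min(stays$date))
    abort("Stays do not cover the survey field weeks.")
  if (panel_size < 1 || panel_size > nrow(persons))
    abort("`panel_size` must be between 1 and the number of persons.")
  set.seed(as.integer(seed))
  cats <- mobility_categories()

  ## true active days per person x wave x category, and zero-trip days
  trips <- dplyr::filter(stays, .data$category != "home")
  wave_of <- function(d) {
    ix <- findInterval(as.numeric(d), as.numeric(schedule$start_date))
    w <- schedule$wave[pmax(ix, 1L)]
    w[ix == 0 | d > schedule$end_date[pmax(ix, 1L)]] <- NA_integer_
    w
  }
  trips <- trips |>
    dplyr::mutate(wave = wave_of(.data$date)) |>
    dplyr::filter(!is.na(.data$wave))
  active <- trips |>
    dplyr::distinct(.data$person_id, .data$wave, .data$category, .data$date) |>
    dplyr::count(.data$person_id, .data$wave, .data$category, name = "n_days")
  anyday <- trips |>
    dplyr::distinct(.data$person_id, .data$wave, .data$date) |>
    dplyr::count(.data$person_id, .data$wave, name = "n_out_days")

  s_wave <- if (!is.null(stringency)) {
    schedule |>
      dplyr::rowwise() |>
      dplyr::mutate(s_mean = mean(stringency$stringency[
        stringency$date >= .data$start_date & stringency$date <= .data$end_date])) |>
      dplyr::ungroup()
  } else dplyr::mutate(schedule, s_mean = 0)

  ## panel membership with attrition and refreshment
  pool <- sample(persons$person_id) # recruitment order
  panel <- pool[seq_len(panel_size)]
  next_new <- panel_size + 1L
  rows <- vector("list", nrow(schedule))
  for (wi in seq_len(nrow(schedule))) {
    w <- schedule$wave[wi]
    resp <- tibble::tibble(respondent_id = sort(panel), wave = w)

    tr <- active[active$wave == w & active$person_id %in% panel, ]
    wide <- matrix(0L, nrow(resp), 9, dimnames = list(NULL, cats))
    if (nrow(tr) > 0) {
      ri <- match(tr$person_id, resp$respondent_id)
      wide[cbind(ri, match(tr$category, cats))] <- tr$n_days
    }
    od <- anyday[anyday$wave == w & anyday$person_id %in% panel, ]
    out_days <- integer(nrow(resp))
    out_days[match(od$person_id, resp$respondent_id)] <- od$n_out_days
    home_days <- 7L - out_days

    shift <- round(model$desirability_shift +
                     model$desirability_stringency_slope * s_wave$s_mean[wi] / 100)
    noisy <- wide + rnorm(length(wide), 0, model$recall_noise_sd)
    codes <- as.integer(pmin(4L, pmax(0L, count_to_code(round(noisy)) - shift)))
    codes[runif(length(codes)) < model$item_nonresponse_prob] <- NA_integer_
    codes <- matrix(codes, nrow(resp), 9, dimnames = list(NULL, survey_item_cols()))

    sh_noisy <- home_days + rnorm(nrow(resp), 0, model$recall_noise_sd)
    ## staying home is the socially desirable direction, so the downward
    ## desirability shift does not apply to this item
    sh <- as.integer(pmin(4L, pmax(0L, count_to_code(round(sh_noisy)))))
    sh[runif(nrow(resp)) < model$item_nonresponse_prob] <- NA_integer_

    rows[[wi]] <- dplyr::bind_cols(resp, tibble::as_tibble(codes),
                                   tibble::tibble(item_stayhome = sh))

    ## attrition then refreshment from never-sampled persons
    stay <- runif(length(panel)) >= model$attrition_prob
    panel <- panel[stay]
    need <- panel_size - length(panel)
    if (need > 0 && next_new <= length(pool)) {
      take <- pool[next_new:min(length(pool), next_new + need - 1L)]
      next_new <- next_new + length(take)
      panel <- c(panel, take)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::left_join(
      dplyr::select(persons, respondent_id = "person_id",
                    "age_group", "gender", "region"),
      by = "respondent_id") |>
    dplyr::relocate("age_group", "gender", "region", .after = "wave")
}

#' Apply the analysis sample filters
#'
#' Drops respondents in the 75+ age group, then applies listwise deletion of
#' responses with any missing value among the nine activity items. The counts
#' dropped by each rule are attached as the `filter_counts` attribute and
#' reported via a message.
#'
#' @param responses Tibble from [administer_survey()].
#' @param drop_age_groups Age-group levels excluded from analysis.
#' @param quiet Suppress the count message.
#' @return Filtered responses (with attribute `filter_counts`).
#' @export
filter_sample <- function(responses, drop_age_groups = "75+", quiet = FALSE) {
  n0 <- nrow(responses)
  kept_age <- dplyr::filter(responses, !.data$age_group %in% drop_age_groups)
  n_age <- n0 - nrow(kept_age)
  items <- as.matrix(kept_age[, survey_item_cols()])
  complete <- rowSums(is.na(items)) == 0
  out <- kept_age[complete, ]
  counts <- c(dropped_age = n_age, dropped_listwise = sum(!complete),
              retained = nrow(out))
  attr(out, "filter_counts") <- counts
  if (!quiet)
    message(sprintf("filter_sample: dropped %d (age), %d (listwise); %d retained from %d.",
                    counts[1], counts[2], counts[3], n0))
  out
}

#' Additive mobility index and subindices
#'
#' The self-report mobility index is the sum of the nine 5-point item codes
#' (range 0-36). Subindices mirror the place categories used for cross-channel
#' comparison: `sub_food_medicine` = food + medicine codes (0-8, compared to
#' grocery & pharmacy), `sub_nonfood` = non-food shopping code (0-4, retail &
#' recreation), `sub_work` = work code (0-4, workplaces).
#'
#' @param responses Filtered responses from [filter_sample()] (no missing
#'   items).
#' @return Tibble `respondent_id`, `wave`, demographics, `index`,
#'   `sub_food_medicine`, `sub_nonfood`, `sub_work`.
#' @export
mobility_index <- function(responses) {
  items <- as.matrix(responses[, survey_item_cols()])
  if (anyNA(items))
    abort("Responses contain missing items; apply `filter_sample()` first.")
  responses |>
    dplyr::transmute(
      .data$respondent_id, .data$wave, .data$age_group, .data$gender, .data$region,
      index = as.integer(rowSums(items)),
      sub_food_medicine = .data$item_food + .data$item_medicine,
      sub_nonfood = .data$item_nonfood,
      sub_work = .data$item_work)
}

#' Wave-level stay-home aggregate
#'
#' Weighted mean of the stay-home frequency code per wave (the survey-side
#' counterpart of the share-of-ROG-above-500 m robustness measure).
#'
#' @param responses Survey responses carrying `item_stayhome`.
#' @param weights Optional tibble `respondent_id`, `wave`, `weight`; equal
#'   weights when `NULL`.
#' @return Tibble `wave`, `value`, `n`.
#' @export
stay_home_measure <- function(responses, weights = NULL) {
  x <- responses
  if (is.null(weights)) {
    x$weight <- 1
  } else {
    x <- dplyr::left_join(x, weights, by = c("respondent_id", "wave"))
  }
  x |>
    dplyr::filter(!is.na(.data$item_stayhome), !is.na(.data$weight)) |>
    dplyr::group_by(.data$wave) |>
    dplyr::summarise(value = sum(.data$weight * .data$item_stayhome) / sum(.data$weight),
                     n = dplyr::n(), .groups = "drop")
}

#' Write / read survey response CSV
#'
#' Columns `respondent_id,wave,age_group,gender,region,item_work,...,item_other,
#' item_stayhome`; blank cells are missing.
#'
#' @param responses Response tibble.
#' @param path File path.
#' @return `write_responses_csv()` returns `path` invisibly.
#' @export
write_responses_csv <- function(responses, path) {
  readr::write_csv(responses, path, na = "")
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    age_group = readr::col_character(),
                    gender = readr::col_character(),
                    region = readr::col_character()))
}
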