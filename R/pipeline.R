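#' Run the full three-channel comparison pipeline
#'
#' Executes the end-to-end analysis for one seeded configuration: simulate the
#' population, stringency, and ground-truth stays; observe them through the
#' GSM, GPS, and survey channels; weight (raking for the survey, target
#' subgroup shares for the pre-aggregated GSM series); harmonize every channel
#' to baseline-relative weekly changes matched to the survey waves; and run the
#' comparison layer (correlations, trend lines, time-fixed-effects regression,
#' and the partial-lockdown difference-in-differences on the non-food-shopping
#' versus food/medicine category pair).
#'
#' Deterministic for a fixed config: the same config and seed reproduce every
#' output byte-for-byte.
#'
#' @param config A [run_config()].
#' @param outdir Output directory; created if needed. `NULL` (default) creates
#'   a timestamped directory `runs/run-<seed>-<timestamp>`.
#' @param write_outputs Write the CSV outputs and log (default `TRUE`); with
#'   `FALSE` the results are only returned.
#' @param quiet Suppress progress messages.
#' @return Object of class `mob_run`: a list with `panel` (the wave-aligned
#'   comparison panel), `correlations`, `trends`, `fe` ([time_fe_regression()]
#'   result), `did` (list per channel), `robustness` (stay-home and
#'   share-above-500 m series), `stringency`, `log`, and `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, write_outputs = TRUE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "mob_run_config"))
  t0 <- Sys.time()
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  ss <- derive_substreams(config$seed, 5)

  ## --- simulate -------------------------------------------------------------
  pop <- stage("population",
               generate_population(config$population, ss[1]))
  stringency <- stage("stringency",
                      simulate_stringency(config$dates, config$stringency_breakpoints))
  say("simulated %d persons; stringency over %d days", nrow(pop), nrow(stringency))
  stays <- stage("stays",
                 simulate_stays(pop, config$model, stringency, config$dates, ss[2]))
  say("simulated %d stays (%d trips)", nrow(stays), sum(stays$category != "home"))

  ## --- GSM channel ----------------------------------------------------------
  gsm_out <- stage("gsm", {
    grid <- tower_grid(config$gsm$spacing_km)
    events <- observe_gsm_events(stays, grid, config$gsm$event_rate_per_hour,
                                 config$gsm$coverage_prob, ss[3])
    rog <- device_day_rog(events) |>
      dplyr::left_join(dplyr::select(pop, device_id = "person_id",
                                     "age_group", "gender", "region"),
                       by = "device_id")
    med <- daily_median_rog(rog, by = c("age_group", "gender"))
    shares <- subgroup_shares(config$targets, c("age_group", "gender"))
    cells <- dplyr::left_join(med, shares, by = c("age_group", "gender"))
    wmean <- function(df, by) {
      df |>
        dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "date")))) |>
        dplyr::summarise(value = weighted_aggregate(.data$median_rog_km, .data$share),
                         .groups = "drop")
    }
    daily <- dplyr::bind_rows(
      wmean(cells, character()) |> dplyr::mutate(subgroup = "population"),
      wmean(cells, "gender") |>
        dplyr::mutate(subgroup = paste0("gender:", .data$gender), gender = NULL),
      wmean(cells, "age_group") |>
        dplyr::mutate(subgroup = paste0("age:", .data$age_group), age_group = NULL))
    share500 <- share_rog_above(rog, 0.5) |>
      dplyr::transmute(.data$date, value = .data$share_above, subgroup = "share_rog_gt_500m")
    list(events = events, rog = rog, daily = daily, share500 = share500)
  })
  say("gsm: %d events, %d device-days", nrow(gsm_out$events), nrow(gsm_out$rog))

  ## --- GPS channel ----------------------------------------------------------
  gps_out <- stage("gps", {
    visits <- observe_place_visits(stays, optin_prob = config$gps$optin_prob,
                                   seed = ss[4])
    daily_measure <- daily_category_measure(visits, config$gps$alpha)
    base <- compute_baseline(daily_measure, config$gps$baseline_start,
                             config$gps$baseline_end)
    pct <- percent_change_vs_baseline(daily_measure, base)
    comp <- composite_gps_index(pct, config$gps$invert_residential)
    ## the channel's level for baseline-week anchoring is the day-of-week
    ## adjusted index 100 + pct (proportional to value / CMR baseline cell)
    cat_map <- c(grocery_and_pharmacy = "category:food_medicine",
                 retail_and_recreation = "category:nonfood",
                 workplaces = "category:work")
    daily <- dplyr::bind_rows(
      comp |> dplyr::transmute(.data$date, value = 100 + .data$composite / 6,
                               subgroup = "population"),
      pct |>
        dplyr::filter(.data$place_category %in% names(cat_map)) |>
        dplyr::transmute(.data$date, value = 100 + .data$pct_change,
                         subgroup = unname(cat_map[.data$place_category])))
    list(visits = visits, daily_measure = daily_measure, pct = pct,
         composite = comp, daily = daily)
  })
  say("gps: %d visits from %d opted-in devices", nrow(gps_out$visits),
      dplyr::n_distinct(gps_out$visits$device_id))

  ## --- survey channel -------------------------------------------------------
  svy <- stage("survey", {
    rmodel <- response_model(
      recall_noise_sd = config$survey$recall_noise_sd,
      desirability_shift = config$survey$desirability_shift,
      desirability_stringency_slope = config$survey$desirability_stringency_slope,
      item_nonresponse_prob = config$survey$item_nonresponse_prob,
      attrition_prob = config$survey$attrition_prob)
    responses <- administer_survey(pop, stays, config$schedule, rmodel, ss[5],
                                   panel_size = config$survey$panel_size,
                                   stringency = stringency)
    filtered <- filter_sample(responses, quiet = TRUE)
    fc <- attr(filtered, "filter_counts")
    say("survey: %d responses from %d respondents; dropped %d (age), %d (listwise)",
        nrow(responses), dplyr::n_distinct(responses$respondent_id),
        fc["dropped_age"], fc["dropped_listwise"])
    idx <- mobility_index(filtered)

    weights <- purrr::map_dfr(sort(unique(filtered$wave)), function(w) {
      sub <- filtered[filtered$wave == w, ]
      rk <- rake_weights(sub, config$targets)
      say("raking wave %d: %d iterations, max margin error %.2e",
          w, rk$iterations, rk$max_margin_error)
      tibble::tibble(respondent_id = sub$respondent_id, wave = w,
                     weight = rk$weights)
    })
    iw <- dplyr::left_join(idx, weights, by = c("respondent_id", "wave"))
    wagg <- function(df, value_col, by = character()) {
      df |>
        dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "wave")))) |>
        dplyr::summarise(value = weighted_aggregate(.data[[value_col]], .data$weight),
                         .groups = "drop")
    }
    wave_vals <- dplyr::bind_rows(
      wagg(iw, "index") |> dplyr::mutate(subgroup = "population"),
      wagg(iw, "index", "gender") |>
        dplyr::mutate(subgroup = paste0("gender:", .data$gender), gender = NULL),
      wagg(iw, "index", "age_group") |>
        dplyr::mutate(subgroup = paste0("age:", .data$age_group), age_group = NULL),
      wagg(iw, "sub_food_medicine") |> dplyr::mutate(subgroup = "category:food_medicine"),
      wagg(iw, "sub_nonfood") |> dplyr::mutate(subgroup = "category:nonfood"),
      wagg(iw, "sub_work") |> dplyr::mutate(subgroup = "category:work"))
    stayhome <- stay_home_measure(filtered, weights) |>
      dplyr::mutate(subgroup = "stay_home")
    list(responses = responses, filtered = filtered, index = idx,
         weights = weights, wave_vals = wave_vals, stayhome = stayhome,
         counts = c(responses = nrow(responses),
                    respondents = dplyr::n_distinct(responses$respondent_id),
                    fc, retained = nrow(filtered)))
  })

  ## --- harmonize ------------------------------------------------------------
  harm <- stage("harmonization", {
    harmonize_daily <- function(daily) {
      d <- if (config$use_moving_average) moving_average(daily) else daily
      weekly_aggregate(d, config$min_days) |>
        relative_change_from_baseline(config$baseline_week) |>
        match_to_waves(config$schedule)
    }
    harmonize_waves <- function(wave_vals) {
      wave_vals |>
        dplyr::left_join(dplyr::select(config$schedule, "wave", week = "start_date"),
                         by = "wave") |>
        dplyr::select("subgroup", "week", "value") |>
        relative_change_from_baseline(config$baseline_week) |>
        match_to_waves(config$schedule)
    }
    panel <- dplyr::bind_rows(
      survey = harmonize_waves(svy$wave_vals),
      gsm = suppressWarnings(harmonize_daily(gsm_out$daily)),
      gps = suppressWarnings(harmonize_daily(gps_out$daily)),
      .id = "channel") |>
      dplyr::transmute(.data$channel, .data$subgroup, .data$wave,
                       .data$week_start, level = .data$value,
                       rel_change_pct = .data$rel_change_pct) |>
      dplyr::arrange(.data$channel, .data$subgroup, .data$wave)
    robustness <- dplyr::bind_rows(
      survey = harmonize_waves(dplyr::select(svy$stayhome, "wave", "value", "subgroup")),
      gsm = suppressWarnings(harmonize_daily(gsm_out$share500)),
      .id = "channel") |>
      dplyr::transmute(.data$channel, .data$subgroup, .data$wave,
                       .data$week_start, level = .data$value,
                       rel_change_pct = .data$rel_change_pct)
    list(panel = panel, robustness = robustness)
  })
  panel <- harm$panel

  ## --- compare --------------------------------------------------------------
  cmp <- stage("comparison", {
    pairwise <- function(chan_x, chan_y, subgroups) {
      purrr::map(subgroups, function(sg) {
        wide <- panel |>
          dplyr::filter(.data$channel %in% c(chan_x, chan_y),
                        .data$subgroup == sg) |>
          dplyr::select("wave", "channel", "rel_change_pct") |>
          tidyr::pivot_wider(names_from = "channel", values_from = "rel_change_pct")
        list(
          cor = pearson_correlation(wide, !!rlang::sym(chan_x), !!rlang::sym(chan_y),
                                    label = paste(chan_x, "vs", chan_y, "|", sg)),
          trend = trend_line(wide, !!rlang::sym(chan_x), !!rlang::sym(chan_y),
                             label = paste(chan_x, "vs", chan_y, "|", sg)))
      })
    }
    demo_sub <- unique(grep("^(gender|age):", panel$subgroup, value = TRUE))
    cat_sub <- unique(grep("^category:", panel$subgroup, value = TRUE))
    res <- c(
      pairwise("survey", "gsm", c("population", demo_sub)),
      pairwise("survey", "gps", c("population", cat_sub)),
      pairwise("gsm", "gps", "population"))
    ## robustness pair: self-reported stay-home vs share of ROG > 500 m
    rob_wide <- harm$robustness |>
      dplyr::select("wave", "channel", "rel_change_pct") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "rel_change_pct")
    res <- c(res, list(list(
      cor = pearson_correlation(rob_wide, !!rlang::sym("survey"), !!rlang::sym("gsm"),
                                label = "stay_home vs share_rog_gt_500m"),
      trend = trend_line(rob_wide, !!rlang::sym("survey"), !!rlang::sym("gsm"),
                         label = "stay_home vs share_rog_gt_500m"))))
    correlations <- purrr::map_dfr(res, ~ tidy(.x$cor))
    trends <- purrr::map_dfr(res, ~ glance(.x$trend) |>
                               dplyr::mutate(label = .x$trend$label, .before = 1))

    fe <- time_fe_regression(
      dplyr::filter(panel, .data$channel %in% c("survey", "gsm"),
                    .data$subgroup %in% demo_sub))

    did_window <- config$did_window_weeks * 7
    did_panel <- panel |>
      dplyr::filter(.data$subgroup %in% c("category:nonfood", "category:food_medicine"),
                    .data$week_start >= config$lockdown_date - did_window,
                    .data$week_start < config$lockdown_date + did_window) |>
      dplyr::mutate(
        group = dplyr::if_else(.data$subgroup == "category:nonfood",
                               "treated", "control"),
        period = dplyr::if_else(.data$week_start < config$lockdown_date,
                                "pre", "post"),
        value = .data$rel_change_pct)
    did <- purrr::map(split(did_panel, did_panel$channel), did_estimate)
    for (ch in names(did))
      say("did [%s]: effect %.2f (SE %.2f)", ch, did[[ch]]$effect, did[[ch]]$se)
    list(correlations = correlations, trends = trends, fe = fe, did = did)
  })

  ## --- write outputs --------------------------------------------------------
  if (write_outputs) {
    if (is.null(outdir))
      outdir <- file.path("runs", sprintf("run-%d-%s", config$seed,
                                          format(t0, "%Y%m%d-%H%M%S")))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    config_to_yaml(config, file.path(outdir, "config.yaml"))
    write_stays_csv(stays, file.path(outdir, "stays.csv"))
    write_events_csv(gsm_out$events, file.path(outdir, "gsm_events.csv"))
    gsm_weekly <- weekly_aggregate(gsm_out$daily, config$min_days)
    readr::write_csv(gsm_weekly, file.path(outdir, "gsm_weekly.csv"))
    readr::write_csv(gps_out$daily_measure, file.path(outdir, "gps_daily.csv"))
    cmr <- gps_out$pct |>
      dplyr::mutate(pct_change = round(.data$pct_change)) |>
      dplyr::select("date", "place_category", "pct_change") |>
      tidyr::pivot_wider(names_from = "place_category", values_from = "pct_change",
                         names_glue = "{place_category}_percent_change_from_baseline") |>
      dplyr::mutate(country_region_code = "XS", country_region = "Synthetica",
                    place_id = "synthetic")
    write_cmr_csv(cmr, file.path(outdir, "cmr_synthetic.csv"))
    write_responses_csv(svy$responses, file.path(outdir, "survey_responses.csv"))
    readr::write_csv(panel, file.path(outdir, "aligned_panel.csv"))
    readr::write_csv(harm$robustness, file.path(outdir, "robustness_panel.csv"))
    readr::write_csv(cmp$correlations, file.path(outdir, "correlations.csv"))
    readr::write_csv(tidy(cmp$fe), file.path(outdir, "fe_regression.csv"))
    did_tbl <- purrr::imap_dfr(cmp$did, ~ tibble::tibble(
      channel = .y, effect = .x$effect, se = .x$se))
    readr::write_csv(did_tbl, file.path(outdir, "did.csv"))
    writeLines(log, file.path(outdir, "log.txt"))
    if (!quiet) message("outputs written to ", outdir)
  }

  structure(
    list(panel = panel, correlations = cmp$correlations, trends = cmp$trends,
         fe = cmp$fe, did = cmp$did, robustness = harm$robustness,
         stringency = stringency, population = pop,
         sample_counts = svy$counts, log = log,
         outdir = if (write_outputs) outdir else NULL,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "mob_run")
}

#' @export
print.mob_run <- function(x, ...) {
  cat(sprintf("<pipeline run> %d aligned panel rows, %.1f s elapsed\n",
              nrow(x$panel), x$elapsed_s))
  cat("correlations (population level):\n")
  print(dplyr::filter(x$correlations, grepl("population", .data$label)))
  invisible(x)
}
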