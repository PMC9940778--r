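# Shared fixture builders; everything is generated in code at test time.

# a flat latent model: same base rate/coef/distance/duration for all categories
flat_model <- function(base = 0.3, coef = 0, noise_sd = 0, seasonal = 0,
                       duration = 1, dist_logmean = log(2), dist_logsd = 0.4) {
  cats <- mobility_categories()
  latent_mobility_model(
    base_rate = setNames(rep(base, 9), cats),
    stringency_coef = setNames(rep(coef, 9), cats),
    seasonal_amplitude = seasonal,
    trip_distance_logmean = setNames(rep(dist_logmean, 9), cats),
    trip_distance_logsd = setNames(rep(dist_logsd, 9), cats),
    trip_duration_mean = setNames(rep(duration, 9), cats),
    noise_sd = noise_sd)
}

const_stringency <- function(dates, level = 0) {
  tibble::tibble(date = sort(as.Date(dates)), stringency = level)
}

# small single-region population (no workplace commuting surprises unless asked)
tiny_population <- function(n = 10, seed = 1, employment = 0) {
  spec <- population_spec(
    n,
    margins = list(age_group = c("14-29" = 0.3, "30-59" = 0.4, "60-74" = 0.3),
                   gender = c(female = 0.5, male = 0.5),
                   region = c(east = 1)),
    employment_rate_by_age = c("14-29" = employment, "30-59" = employment,
                               "60-74" = employment))
  generate_population(spec, seed)
}

# independent two-pass ROG oracle: explicit center, explicit weighted mean of
# squared distances, computed with plain loops
rog_oracle <- function(x, y, w) {
  W <- 0; cx <- 0; cy <- 0
  for (i in seq_along(x)) {
    W <- W + w[i]; cx <- cx + w[i] * x[i]; cy <- cy + w[i] * y[i]
  }
  cx <- cx / W; cy <- cy / W
  acc <- 0
  for (i in seq_along(x)) acc <- acc + w[i] * ((x[i] - cx)^2 + (y[i] - cy)^2)
  sqrt(acc / W)
}

# classic IPF on the cell-count table (alternating projection oracle): adjusts
# cell totals to match each variable's target margin in turn
ipf_table_oracle <- function(tab, targets, n_iter = 200) {
  w <- tab / sum(tab) # cell proportions
  dims <- seq_along(dim(tab))
  for (it in seq_len(n_iter)) {
    for (d in dims) {
      marg <- apply(w, d, sum)
      adj <- targets[[d]] / marg
      adj[!is.finite(adj)] <- 1
      w <- sweep(w, d, adj, `*`)
    }
  }
  w
}

# random CMR-style records with missing cells
random_cmr_records <- function(n = 25, seed = 1, na_prob = 0.15) {
  set.seed(seed)
  rec <- tibble::tibble(date = as.Date("2020-02-15") + seq_len(n) - 1)
  for (cc in paste0(place_categories(), "_percent_change_from_baseline")) {
    v <- sample(-80:60, n, replace = TRUE)
    v[runif(n) < na_prob] <- NA
    rec[[cc]] <- as.numeric(v)
  }
  rec$country_region_code <- "XS"
  rec$country_region <- "Synthetica"
  rec
}

# small end-to-end configuration: 8 weekly waves, 20 simulated weeks
small_run_config <- function(seed = 11, n_persons = 60, ...) {
  run_config(seed = seed, n_persons = n_persons, n_weeks = 20,
             schedule = wave_schedule(n_waves = 8),
             lockdown_date = as.Date("2020-04-13"),
             did_window_weeks = 3, ...)
}
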