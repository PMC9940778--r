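#' Pearson correlation between two channels
#'
#' Product-moment correlation over pairwise-complete observations with a
#' two-sided p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (via [stats::cor.test()]); `|r| = 1` reports `p = 0`.
#'
#' @param data Data frame.
#' @param x,y Columns to correlate (tidy-eval).
#' @param label Optional subgroup/category label carried into the result.
#' @return Object of class `mob_cor` with fields `r`, `n`, `statistic`,
#'   `p_value`, `label`; see [tidy.mob_cor()].
#' @export
#' @examples
#' pearson_correlation(data.frame(a = 1:4, b = c(1, 3, 2, 4)), a, b)
pearson_correlation <- function(data, x, y, label = NA_character_) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- complete.cases(xv, yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("Need at least 3 pairwise-complete observations.")
  if (sd(xv) == 0 || sd(yv) == 0)
    abort("Correlation undefined: one series has zero variance.")
  ct <- suppressWarnings(stats::cor.test(xv, yv, alternative = "two.sided",
                                         method = "pearson"))
  r <- unname(ct$estimate)
  p <- if (abs(abs(r) - 1) < 1e-15) 0 else unname(ct$p.value)
  structure(list(r = r, n = n, statistic = unname(ct$statistic),
                 p_value = p, label = label),
            class = "mob_cor")
}

#' @export
print.mob_cor <- function(x, ...) {
  cat(sprintf("<correlation%s> r = %.3f, n = %d, p = %.4g (2-sided)\n",
              if (is.na(x$label)) "" else paste0(": ", x$label),
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Tidy a correlation result
#'
#' @param x A `mob_cor` object.
#' @param ... Unused.
#' @return One-row tibble `label`, `r`, `n`, `statistic`, `p_value`.
#' @export
tidy.mob_cor <- function(x, ...) {
  tibble::tibble(label = x$label, r = x$r, n = x$n,
                 statistic = x$statistic, p_value = x$p_value)
}

#' @export
glance.mob_cor <- function(x, ...) tidy(x)[, c("r", "n", "p_value")]

#' Trend line between two channels' relative changes
#'
#' Ordinary least squares fit of `y` on `x`; a slope near 1 with intercept near
#' 0 means the two channels move 1:1 on the relative-change scale.
#'
#' @inheritParams pearson_correlation
#' @return Object of class `mob_trend` wrapping the `lm` fit, with `slope`,
#'   `intercept`, `sigma` (residual standard error).
#' @export
trend_line <- function(data, x, y, label = NA_character_) {
  df <- tibble::tibble(x = dplyr::pull(data, {{ x }}),
                       y = dplyr::pull(data, {{ y }}))
  df <- df[complete.cases(df), ]
  if (nrow(df) < 2) abort("Need at least 2 complete observations.")
  if (sd(df$x) == 0) abort("Trend line undefined: x is constant.")
  fit <- lm(y ~ x, data = df)
  structure(list(fit = fit, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 sigma = summary(fit)$sigma, n = nrow(df), label = label),
            class = "mob_trend")
}

#' @export
print.mob_trend <- function(x, ...) {
  cat(sprintf("<trend line%s> slope = %.3f, intercept = %.3f, RSE = %.3f, n = %d\n",
              if (is.na(x$label)) "" else paste0(": ", x$label),
              x$slope, x$intercept, x$sigma, x$n))
  invisible(x)
}

#' @export
tidy.mob_trend <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(label = x$label, term = c("intercept", "slope"),
                 estimate = unname(s[, 1]), se = unname(s[, 2]),
                 statistic = unname(s[, 3]), p_value = unname(s[, 4]))
}

#' @export
glance.mob_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, sigma = x$sigma,
                 r_squared = summary(x$fit)$r.squared, n = x$n)
}

#' Time-fixed-effects regression on the aligned panel
#'
#' OLS of relative change on channel indicators, subgroup indicators, their
#' interactions, and one indicator per wave (the time fixed effects, which
#' absorb the common trend). Reference levels are the first channel, first
#' subgroup and first wave; channel and interaction coefficients then quantify
#' level and subgroup-profile differences between channels net of the common
#' time path.
#'
#' @param panel Long tibble with columns `channel`, `wave`, `rel_change_pct`
#'   and optionally `subgroup`.
#' @return Object of class `mob_fe` wrapping the `lm` fit.
#' @export
time_fe_regression <- function(panel) {
  need <- c("channel", "wave", "rel_change_pct")
  stopifnot(all(need %in% names(panel)))
  panel <- dplyr::filter(panel, !is.na(.data$rel_change_pct))
  if (dplyr::n_distinct(panel$wave) < 2)
    abort("Need at least 2 waves: time fixed effects are otherwise collinear with the intercept.")
  if (dplyr::n_distinct(panel$channel) < 2)
    abort("Need at least 2 channels.")
  panel$channel <- factor(panel$channel)
  panel$wave_f <- factor(panel$wave)
  has_sub <- "subgroup" %in% names(panel) &&
    dplyr::n_distinct(panel$subgroup) > 1
  fml <- if (has_sub) {
    panel$subgroup <- factor(panel$subgroup)
    rel_change_pct ~ channel * subgroup + wave_f
  } else {
    rel_change_pct ~ channel + wave_f
  }
  fit <- lm(fml, data = panel)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Design is rank deficient; aliased term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  structure(list(fit = fit, n = nrow(panel),
                 channels = levels(panel$channel),
                 df_residual = fit$df.residual),
            class = "mob_fe")
}

#' @export
print.mob_fe <- function(x, ...) {
  cat(sprintf("<time-FE regression> %d obs, channels: %s; residual df = %d\n",
              x$n, paste(x$channels, collapse = ", "), x$df_residual))
  td <- tidy(x)
  print(td[!grepl("^wave_f", td$term), ], n = 20)
  invisible(x)
}

#' @export
tidy.mob_fe <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 se = unname(s[, 2]), statistic = unname(s[, 3]),
                 p_value = unname(s[, 4]))
}

#' @export
glance.mob_fe <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma, df_residual = x$df_residual, n = x$n)
}

#' Difference-in-differences estimate
#'
#' Two-group, two-period DiD:
#' `effect = (mean treated post - mean treated pre) - (mean control post - mean control pre)`,
#' computed from cell means, with the standard error taken from the interaction
#' term of the equivalent two-way OLS `value ~ group * period` (to which the
#' cell-means effect is identical).
#'
#' @param panel Tibble with columns `group` (values `"treated"`/`"control"`),
#'   `period` (`"pre"`/`"post"`), `value`.
#' @return Object of class `mob_did` with `effect`, `se`, `cell_means`, the
#'   `lm` fit, and cell counts.
#' @export
#' @examples
#' p <- tidyr::expand_grid(group = c("treated", "control"),
#'                         period = c("pre", "post"), rep = 1:3)
#' p$value <- c(6, 6, 6, 10, 10, 10, 9, 9, 9, 10, 10, 10)
#' did_estimate(p)$effect # -3
did_estimate <- function(panel) {
  stopifnot(all(c("group", "period", "value") %in% names(panel)))
  panel <- dplyr::filter(panel, !is.na(.data$value))
  if (!all(panel$group %in% c("treated", "control")))
    abort("`group` must be 'treated' or 'control'.")
  if (!all(panel$period %in% c("pre", "post")))
    abort("`period` must be 'pre' or 'post'.")
  cells <- tidyr::expand_grid(group = c("treated", "control"),
                              period = c("pre", "post"))
  cm <- panel |>
    dplyr::group_by(.data$group, .data$period) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  cm <- dplyr::left_join(cells, cm, by = c("group", "period"))
  if (anyNA(cm$mean)) {
    empty <- cm[is.na(cm$mean), ]
    abort(paste0("Empty DiD cell(s): ",
                 paste(empty$group, empty$period, sep = "/", collapse = ", ")))
  }
  getm <- function(g, p) cm$mean[cm$group == g & cm$period == p]
  effect <- (getm("treated", "post") - getm("treated", "pre")) -
    (getm("control", "post") - getm("control", "pre"))
  panel$group_f <- factor(panel$group, c("control", "treated"))
  panel$period_f <- factor(panel$period, c("pre", "post"))
  fit <- lm(value ~ group_f * period_f, data = panel)
  se <- if (fit$df.residual > 0)
    summary(fit)$coefficients["group_ftreated:period_fpost", 2] else NA_real_
  structure(list(effect = effect, se = unname(se), cell_means = cm, fit = fit),
            class = "mob_did")
}

#' @export
print.mob_did <- function(x, ...) {
  cat(sprintf("<difference-in-differences> effect = %.3f (SE %.3f)\n",
              x$effect, x$se))
  print(x$cell_means)
  invisible(x)
}

#' @export
tidy.mob_did <- function(x, ...) {
  tibble::tibble(term = "did_effect", estimate = x$effect, se = x$se)
}

#' @export
glance.mob_did <- function(x, ...) {
  tibble::tibble(effect = x$effect, se = x$se, n = sum(x$cell_means$n))
}

#' Simulate a pair of channels observing weekly trends
#'
#' Small-scale generator for correlation-recovery studies. With
#' `shared = TRUE`, both channels observe the same latent weekly trend — a
#' regime-shaped pandemic course (baseline lockdown, high summer plateau,
#' second lockdown; policy switches are abrupt, so the trend is piecewise
#' constant) — each with independent Gaussian noise whose SD is `noise_frac`
#' times the trend range. With `shared = FALSE` each channel observes its own
#' independently drawn weakly autocorrelated (AR(1), phi = 0.3) latent trend.
#'
#' @param n_waves Number of waves (default 22).
#' @param noise_frac Noise SD as a fraction of the trend range (default 0.1).
#' @param shared Do both channels observe the same latent trend?
#' @param seed Integer seed.
#' @return Tibble `wave`, `x`, `y`.
#' @export
simulate_trend_pair <- function(n_waves = 22, noise_frac = 0.1, shared = TRUE,
                                seed = 1) {
  set.seed(as.integer(seed))
  t <- seq_len(n_waves)
  if (shared) {
    ## relative mobility change: first lockdown (baseline), summer plateau,
    ## second lockdown
    breaks <- round(c(0.25, 0.8) * n_waves)
    trend <- ifelse(t <= breaks[1], 0, ifelse(t <= breaks[2], 85, 5))
    rng <- diff(range(trend))
    tibble::tibble(wave = t,
                   x = trend + rnorm(n_waves, 0, noise_frac * rng),
                   y = trend + rnorm(n_waves, 0, noise_frac * rng))
  } else {
    ar1 <- function() {
      z <- numeric(n_waves)
      e <- rnorm(n_waves)
      z[1] <- e[1]
      for (i in 2:n_waves) z[i] <- 0.3 * z[i - 1] + e[i]
      (z - mean(z)) / max(sd(z), 1e-12) * 20
    }
    t1 <- ar1()
    t2 <- ar1()
    tibble::tibble(wave = t,
                   x = t1 + rnorm(n_waves, 0, noise_frac * diff(range(t1))),
                   y = t2 + rnorm(n_waves, 0, noise_frac * diff(range(t2))))
  }
}
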