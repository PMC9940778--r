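test_that("correlation handles perfect, inverse, and hand-computed cases", {
  expect_equal(pearson_correlation(data.frame(x = 1:3, y = c(2, 4, 6)), x, y)$r, 1)
  expect_equal(pearson_correlation(data.frame(x = 1:3, y = c(6, 4, 2)), x, y)$r, -1)
  expect_equal(pearson_correlation(data.frame(x = 1:3, y = c(2, 4, 6)), x, y)$p_value, 0)

  # x=(1,2,3,4), y=(1,3,2,4): r = 0.8, t = 0.8*sqrt(2)/sqrt(0.36), df = 2
  ct <- pearson_correlation(data.frame(x = 1:4, y = c(1, 3, 2, 4)), x, y)
  expect_equal(ct$r, 0.8, tolerance = 1e-12)
  t_exp <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(ct$statistic, t_exp, tolerance = 1e-12)
  expect_equal(ct$p_value, 2 * pt(-t_exp, df = 2), tolerance = 1e-12)
  expect_equal(round(ct$p_value, 3), 0.2)
})

test_that("correlation agrees with the covariance/variance oracle", {
  set.seed(70)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    d <- data.frame(x = rnorm(n), y = rnorm(n))
    r_oracle <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
      sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
    expect_equal(pearson_correlation(d, x, y)$r, r_oracle, tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs raise errors", {
  expect_error(pearson_correlation(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
  expect_error(pearson_correlation(data.frame(x = 1:2, y = 2:3), x, y),
               "at least 3")
  # pairwise-complete: NA rows are dropped before the n check
  d <- data.frame(x = c(1, 2, 3, NA), y = c(2, 4, 6, 1))
  expect_equal(pearson_correlation(d, x, y)$n, 3L)
})

test_that("trend lines recover exact linear relationships", {
  # exact fits below: lm's perfect-fit warning is expected
  tl <- suppressWarnings(trend_line(data.frame(x = c(0, 1, 2), y = c(0, 1, 2)), x, y))
  expect_equal(tl$slope, 1, tolerance = 1e-12)
  expect_equal(tl$intercept, 0, tolerance = 1e-12)
  tl2 <- suppressWarnings(trend_line(data.frame(x = c(0, 1, 2), y = c(1, 3, 5)), x, y))
  expect_equal(tl2$slope, 2, tolerance = 1e-12)
  expect_equal(tl2$intercept, 1, tolerance = 1e-12)
  expect_error(trend_line(data.frame(x = c(2, 2), y = 1:2), x, y), "constant")
  expect_named(suppressWarnings(tidy(tl2)),
               c("label", "term", "estimate", "se", "statistic", "p_value"))
})

test_that("time-FE regression absorbs common trends and recovers level shifts", {
  waves <- 1:10
  trend <- sin(waves) * 20
  panel <- dplyr::bind_rows(
    tibble::tibble(channel = "a", wave = waves, rel_change_pct = trend),
    tibble::tibble(channel = "b", wave = waves, rel_change_pct = trend + 5))
  fit <- time_fe_regression(panel)
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "channelb"], 5, tolerance = 1e-10)

  # identical series: all channel coefficients zero
  panel2 <- dplyr::mutate(panel, rel_change_pct = rep(trend, 2))
  td2 <- suppressWarnings(tidy(time_fe_regression(panel2)))
  expect_equal(td2$estimate[td2$term == "channelb"], 0, tolerance = 1e-10)

  expect_error(time_fe_regression(dplyr::filter(panel, wave == 1)),
               "at least 2 waves")
  expect_error(time_fe_regression(dplyr::filter(panel, channel == "a")),
               "2 channels")
})

test_that("FE interactions quantify subgroup differences between channels", {
  set.seed(72)
  waves <- 1:8
  trend <- cumsum(rnorm(8))
  mk <- function(ch, sg, shift) tibble::tibble(
    channel = ch, subgroup = sg, wave = waves, rel_change_pct = trend + shift)
  panel <- dplyr::bind_rows(mk("a", "g1", 0), mk("a", "g2", 0),
                            mk("b", "g1", 0), mk("b", "g2", 3))
  td <- suppressWarnings(tidy(time_fe_regression(panel)))
  expect_equal(td$estimate[td$term == "channelb:subgroupg2"], 3,
               tolerance = 1e-10)
})

test_that("DiD cell-means estimate matches the textbook case and the OLS term", {
  p <- tidyr::expand_grid(group = c("treated", "control"),
                          period = c("pre", "post"), rep = 1:3)
  p$value <- dplyr::case_when(
    p$group == "treated" & p$period == "pre" ~ 10,
    p$group == "treated" & p$period == "post" ~ 6,
    p$group == "control" & p$period == "pre" ~ 10,
    TRUE ~ 9)
  d <- suppressWarnings(did_estimate(p))
  expect_equal(d$effect, -3)

  # parallel trends, no treatment
  p2 <- dplyr::mutate(p, value = ifelse(period == "post", 5, 8))
  expect_equal(suppressWarnings(did_estimate(p2))$effect, 0)

  expect_error(did_estimate(dplyr::filter(p, !(group == "control" & period == "post"))),
               "control/post")

  # random panels: cell-means formula equals the OLS interaction coefficient
  set.seed(71)
  for (i in 1:10) {
    rp <- tidyr::expand_grid(group = c("treated", "control"),
                             period = c("pre", "post"),
                             rep = seq_len(sample(2:6, 1)))
    rp$value <- rnorm(nrow(rp), sd = 5)
    dd <- did_estimate(rp)
    ols <- coef(lm(value ~ factor(group, c("control", "treated")) *
                     factor(period, c("pre", "post")), data = rp))
    expect_equal(dd$effect, unname(ols[4]), tolerance = 1e-10)
  }
})

test_that("two-channel FE regression is consistent with the channel shift", {
  # when channel b = a + c at every wave, the FE channel coefficient equals
  # the intercept of the trend line of b on a shifted by (1 - slope) * mean
  set.seed(73)
  waves <- 1:12
  trend <- cumsum(rnorm(12, sd = 4))
  panel <- dplyr::bind_rows(
    tibble::tibble(channel = "a", wave = waves, rel_change_pct = trend),
    tibble::tibble(channel = "b", wave = waves, rel_change_pct = trend + 7))
  fe <- suppressWarnings(tidy(time_fe_regression(panel)))
  tl <- suppressWarnings(trend_line(tibble::tibble(x = trend, y = trend + 7), x, y))
  expect_equal(fe$estimate[fe$term == "channelb"], 7, tolerance = 1e-10)
  expect_equal(tl$slope, 1, tolerance = 1e-10)
  expect_equal(tl$intercept, 7, tolerance = 1e-10)
})

test_that("tidy and glance methods return well-formed summaries", {
  d <- data.frame(x = 1:6, y = c(1.2, 2.1, 2.8, 4.4, 4.9, 6.1))
  ct <- pearson_correlation(d, x, y, label = "demo")
  expect_equal(tidy(ct)$label, "demo")
  expect_named(glance(ct), c("r", "n", "p_value"))
  tl <- trend_line(d, x, y)
  expect_named(glance(tl), c("slope", "intercept", "sigma", "r_squared", "n"))
})
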