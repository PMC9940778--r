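#' Poststratification raking weights (iterative proportional fitting)
#'
#' Computes unit weights so that the weighted marginal distribution of each
#' weighting variable matches its population target. The algorithm cycles over
#' the variables in their declared order, each pass multiplying weights by
#' `target / weighted proportion` per level, until every weighted margin is
#' within `tol` of its target. Weights are normalized to mean 1.
#'
#' @param data Data frame with one row per unit, containing every variable in
#'   `targets` as a categorical column.
#' @param targets Named list of named target-proportion vectors (each summing
#'   to 1), e.g. `list(gender = c(female = .5, male = .5))`, or a data frame
#'   with columns `variable`, `level`, `target`.
#' @param tol Convergence tolerance on the margins (default 1e-6).
#' @param max_iter Maximum IPF cycles (default 100).
#' @param trim_bounds Optional length-2 numeric: weights are clamped to these
#'   bounds after convergence and renormalized (which can reopen small margin
#'   gaps; off by default).
#' @return Object of class `mob_raking`: a list with `weights` (numeric, mean
#'   1, same order as `data`), `iterations`, `max_margin_error`, `converged`.
#' @export
#' @examples
#' d <- data.frame(gender = rep(c("f", "m"), each = 50))
#' rake_weights(d, list(gender = c(f = 0.6, m = 0.4)))$weights[c(1, 51)]
rake_weights <- function(data, targets, tol = 1e-6, max_iter = 100,
                         trim_bounds = NULL) {
  if (is.data.frame(targets)) {
    stopifnot(all(c("variable", "level", "target") %in% names(targets)))
    targets <- split(setNames(targets$target, targets$level), targets$variable)
  }
  if (!is.list(targets) || is.null(names(targets)))
    abort("`targets` must be a named list of target-proportion vectors.")
  purrr::iwalk(targets, check_margin)
  miss <- setdiff(names(targets), names(data))
  if (length(miss) > 0)
    abort(paste0("Weighting variable(s) absent from data: ",
                 paste(miss, collapse = ", ")))
  n <- nrow(data)
  fct <- purrr::imap(targets, function(tg, v) {
    x <- as.character(data[[v]])
    extra <- setdiff(unique(x), names(tg))
    if (length(extra) > 0)
      abort(sprintf("Variable `%s` has level(s) without a target: %s.",
                    v, paste(extra, collapse = ", ")))
    empty <- names(tg)[tg > 0 & !(names(tg) %in% x)]
    if (length(empty) > 0)
      abort(sprintf("Infeasible: positive target on empty sample level(s) of `%s`: %s.",
                    v, paste(empty, collapse = ", ")))
    factor(x, levels = names(tg))
  })

  w <- rep(1, n)
  margin_error <- function(w) {
    max(purrr::map_dbl(names(targets), function(v) {
      prop <- tapply(w, fct[[v]], sum, default = 0) / sum(w)
      max(abs(prop - targets[[v]]))
    }))
  }
  it <- 0L
  err <- margin_error(w)
  while (err > tol && it < max_iter) {
    it <- it + 1L
    for (v in names(targets)) {
      prop <- tapply(w, fct[[v]], sum, default = 0) / sum(w)
      adj <- as.numeric(ifelse(prop > 0, targets[[v]] / prop, 1))
      w <- w * adj[as.integer(fct[[v]])]
    }
    err <- margin_error(w)
  }
  if (err > tol)
    abort(sprintf("Raking did not converge in %d iterations (worst margin gap %.3g).",
                  max_iter, err))
  if (!is.null(trim_bounds)) {
    stopifnot(length(trim_bounds) == 2, trim_bounds[1] > 0,
              trim_bounds[2] >= trim_bounds[1])
    w <- pmin(pmax(w / mean(w), trim_bounds[1]), trim_bounds[2])
    err <- margin_error(w)
  }
  w <- unname(w / mean(w))
  structure(list(weights = w, iterations = it, max_margin_error = err,
                 converged = TRUE),
            class = "mob_raking")
}

#' @export
print.mob_raking <- function(x, ...) {
  cat(sprintf("<raking weights> n = %d, %d iterations, max margin error %.2e\n",
              length(x$weights), x$iterations, x$max_margin_error))
  cat(sprintf("  weight range [%.3f, %.3f], mean %.6f\n",
              min(x$weights), max(x$weights), mean(x$weights)))
  invisible(x)
}

#' Weighted aggregate of unit values
#'
#' `sum(w * v) / sum(w)` with pairwise exclusion of missing values (a missing
#' value drops its weight too).
#'
#' @param values Numeric (or logical, for proportions) vector.
#' @param weights Positive weights, recycled if length 1.
#' @param statistic `"mean"` or `"proportion"` (values must be 0/1 or logical).
#' @return A single number; `NA` when no non-missing value remains.
#' @export
weighted_aggregate <- function(values, weights = 1,
                               statistic = c("mean", "proportion")) {
  statistic <- rlang::arg_match(statistic)
  weights <- rep_len(weights, length(values))
  if (statistic == "proportion") {
    values <- as.numeric(values)
    if (!all(values %in% c(0, 1) | is.na(values)))
      abort("`proportion` requires 0/1 or logical values.")
  }
  keep <- !is.na(values) & !is.na(weights)
  if (!any(keep)) return(NA_real_)
  sum(weights[keep] * values[keep]) / sum(weights[keep])
}

#' Subgroup shares implied by independent margins
#'
#' Joint target shares for crossed subgroups under independence of the margins
#' (the weighting convention for pre-aggregated GSM subgroup series, where
#' unit-level attributes are unavailable and weights enter as subgroup shares).
#'
#' @param targets Named list of margin vectors (see [rake_weights()]).
#' @param variables Which margin variables to cross (default all).
#' @return Tibble with one column per variable and a `share` column summing
#'   to 1.
#' @export
subgroup_shares <- function(targets, variables = names(targets)) {
  purrr::iwalk(targets[variables], check_margin)
  grids <- purrr::map(targets[variables], names)
  out <- tidyr::expand_grid(!!!grids)
  out$share <- purrr::reduce(variables, .init = rep(1, nrow(out)),
                             function(acc, v) acc * unname(targets[[v]][out[[v]]]))
  out
}

#' Targets CSV I/O
#'
#' Long format `variable,level,target`.
#'
#' @param path CSV path.
#' @param targets Named list of margins.
#' @return `read_targets_csv()` returns the named-list form.
#' @export
read_targets_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("variable", "level", "target") %in% names(x)))
  split(setNames(x$target, x$level), x$variable)
}

#' @rdname read_targets_csv
#' @export
write_targets_csv <- function(targets, path) {
  out <- purrr::imap_dfr(targets, ~ tibble::tibble(
    variable = .y, level = names(.x), target = unname(.x)))
  readr::write_csv(out, path)
  invisible(path)
}
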