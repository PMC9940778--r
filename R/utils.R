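## Internal helpers: seed substreams, rounding, validation.

#' Derive reproducible sub-seeds from one master seed
#'
#' Expands a single integer seed into `n` independent substream seeds so that
#' per-unit simulation (one stream per person/device) does not depend on the
#' order units are processed in.
#'
#' @param seed Master integer seed.
#' @param n Number of substreams.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_substreams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Per-unit substream seed keyed on the unit id
#'
#' Deterministic hash of `(seed, id)` into a valid seed, so a unit's RNG
#' substream depends only on the master seed and its own id — not on how many
#' other units are simulated or in what order.
#'
#' @param seed Master integer seed.
#' @param id Integer unit id(s).
#' @return Integer seed(s) in `[1, 2^31 - 1]`.
#' @keywords internal
unit_stream_seed <- function(seed, id) {
  m <- 2147483647 # 2^31 - 1 (prime)
  as.integer(((as.numeric(seed) %% m) * 48271 + as.numeric(id) * 16807) %% m + 1)
}

#' Largest-remainder rounding of proportions to integer counts
#'
#' Allocates `n` units to levels so counts sum exactly to `n`: each level gets
#' `floor(n * p)` and the remaining units go to the largest fractional
#' remainders (ties broken by position, deterministically).
#'
#' @param n Total count.
#' @param props Numeric proportions summing to 1.
#' @return Integer counts, same length and names as `props`, summing to `n`.
#' @export
#' @examples
#' largest_remainder(10, c(0.3, 0.4, 0.3))
largest_remainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  if (abs(sum(props) - 1) > 1e-9)
    abort("`props` must sum to 1.")
  raw <- n * props
  counts <- floor(raw)
  short <- round(n - sum(counts))
  if (short > 0) {
    frac <- raw - counts
    take <- order(-frac, seq_along(frac))[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

## Checks one margin vector: named, in [0,1], sums to 1.
check_margin <- function(m, what) {
  if (is.null(names(m)) || any(!nzchar(names(m))))
    abort(sprintf("Margin `%s` must be a named vector.", what))
  if (any(m < 0 | m > 1))
    abort(sprintf("Margin `%s` has proportions outside [0, 1].", what))
  if (abs(sum(m) - 1) > 1e-9)
    abort(sprintf("Margin `%s` must sum to 1 (got %.12f).", what, sum(m)))
  invisible(m)
}

## Monday of the ISO week containing `date`.
iso_week_start <- function(date) {
  date <- as.Date(date)
  dow <- as.integer(format(date, "%u")) # 1 = Monday
  date - (dow - 1L)
}

is_date_scalar <- function(x) inherits(x, "Date") && length(x) == 1 && !is.na(x)
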