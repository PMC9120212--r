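#' @keywords internal
"_PACKAGE"

## Typed condition helper: all package errors carry class "delimatch_error"
## plus a finer subclass so callers can discriminate input vs. numerical
## failures programmatically.
dm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "delimatch_error", "error"),
                      call = call))
}

dm_assert <- function(cond, msg, class = "input_error") {
  if (!isTRUE(cond)) dm_stop(msg, class, call = sys.call(-1))
}

#' Round to two decimals, half to even
#'
#' Report-level rounding used for match-ratio tables. Base `round()` already
#' rounds half to even at representable midpoints; this wrapper fixes the
#' number of digits at 2 and guards against floating noise at the third
#' decimal.
#'
#' @param x numeric vector.
#' @return `x` rounded to two decimal places.
#' @export
round2 <- function(x) round(round(x, 10), 2)

#' Truncate to two decimals
#'
#' The alternative table convention (round toward zero); some published
#' congruence tables mix truncation and rounding, so both are exposed.
#'
#' @param x numeric vector.
#' @return `x` truncated to two decimal places.
#' @export
trunc2 <- function(x) trunc(round(x, 10) * 100) / 100

## Deterministic RNG scope: evaluates expr with the given seed without
## clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
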