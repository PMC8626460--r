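# Internal helpers shared across modules.

sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions never disturb the session stream. All package
#' randomness flows through this helper, which is the documented
#' seed-splitting scheme: a function that needs k independent substreams
#' derives them as `seed + 0 .. seed + k-1` (callers keep seeds below
#' 2^31 - k).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Monday on or before each date: the anchor for weekly (ISO-style) bins.
monday_floor <- function(dates) {
  d <- as.Date(dates)
  d - (as.integer(format(d, "%u")) - 1L)
}

#' Assign timestamps to Monday-anchored weekly bins
#'
#' Bins are half-open `[monday, monday + 7d)` and indexed from the Monday on
#' or before the earliest timestamp (or an explicit `anchor`).
#'
#' @param timestamps `POSIXct`/`Date` vector.
#' @param anchor optional `Date`; defaults to the Monday floor of the minimum.
#' @return list with integer `week` (0-based), `anchor` date.
#' @export
week_bins <- function(timestamps, anchor = NULL) {
  d <- as.Date(timestamps, tz = "UTC")
  if (is.null(anchor)) anchor <- monday_floor(min(d))
  anchor <- as.Date(anchor)
  list(week = as.integer(floor(as.numeric(d - anchor) / 7)), anchor = anchor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
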