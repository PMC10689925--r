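## Internal helpers shared across modules.

#' Round half up
#'
#' Rounds to the nearest integer with ties going away from zero towards the
#' next larger integer (0.5 -> 1, 3.5 -> 4). Used wherever a continuous
#' summary (median, scaled SF) must be mapped back onto the ordinal 0-5
#' seizure-frequency grid; base `round()` rounds half to even, which would
#' leave the grid asymmetrically.
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

## longest run of TRUE in a logical vector (0 if none)
max_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
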