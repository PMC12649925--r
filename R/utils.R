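# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so seeded package functions never
#' disturb the caller's random number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed: every seeded stage derives child seeds from
# one top-level seed so stage-level reruns reproduce.  Kept strictly below
# 2^31 to stay a valid R integer.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587) + 1L
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single value in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

# geometric mean of strictly positive values
geom_mean <- function(x) exp(mean(log(x)))
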