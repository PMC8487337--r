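# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Named, independent substreams derived from one global seed, so extra draws
# in one stage never perturb another stage's stream. The mapping is a fixed
# multiplicative hash, documented here and relied on by the run_* functions.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Round half away from zero
#'
#' Display rounding used for printed percentages and percentage-point
#' differences: ties go away from zero (0.15 -> 0.2, -0.15 -> -0.2), unlike
#' [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_away(0.15, 1)   # 0.2
#' round_half_away(-14.75, 1) # -14.8
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Geometric mean and geometric coefficient of variation
#'
#' The geometric CV is `100 * sqrt(exp(s2) - 1)` where `s2` is the sample
#' variance (n - 1 denominator) of `log(x)`. For a single value the
#' dispersion is undefined and reported as 0.
#'
#' @param x strictly positive numeric vector.
#' @return list with `n`, `geometric_mean`, `geometric_cv_percent`.
#' @export
geo_stats <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric summaries require strictly positive finite values")
  }
  lx <- log(x)
  gcv <- if (length(x) < 2L) 0 else 100 * sqrt(exp(stats::var(lx)) - 1)
  list(n = length(x), geometric_mean = exp(mean(lx)), geometric_cv_percent = gcv)
}

stop_input <- function(...) stop(..., call. = FALSE)
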