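#' Round half away from zero
#'
#' Rounding convention used by every reporting table in the package:
#' digits decimal places, ties rounded up in magnitude (so 0.125 -> 0.13 at
#' two digits), applied to the double-precision value as represented.
#' Internal computation is never rounded; only the reporting layer calls this.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 2).
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(2.345, 2.344, -2.345))
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a numerator over a denominator, reporting convention
#'
#' Computes `100 * num / den` and rounds half-up to `digits` decimals.
#' This is the single place percentages are formed for tables, so every
#' emitted ratio follows one convention.
#'
#' @param num,den numeric vectors (recycled).
#' @param digits decimal places (default 2).
#' @return numeric percentage(s).
#' @examples
#' ratioPercent(3.989, 6.246)  # 63.86
#' ratioPercent(126, 233, digits = 0)  # 54
#' @export
ratioPercent <- function(num, den, digits = 2) {
  if (any(den == 0)) stop("ratioPercent: zero denominator")
  roundHalfUp(100 * num / den, digits)
}

## Run `expr` under a temporary RNG state seeded with `seed`; restores the
## caller's .Random.seed so generators are deterministic per call and do not
## disturb the session RNG stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stage-specific seed below 2^31 from a base seed, so each
## generator stage has its own reproducible stream.
stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 7919L
}

stopifnotScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("%s must be a single positive number", name))
  }
  invisible(TRUE)
}
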