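# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive per-unit child seeds from a master seed (deterministic, < 2^31)
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Numerically stable softplus
#' @noRd
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random unit vector of length n
#' @noRd
runit <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

#' Unit vector at a given angle from `u`, in the plane spanned by u and a
#' random direction orthogonal to it
#' @noRd
unit_at_angle <- function(u, angle) {
  n <- length(u)
  if (n < 2 && angle > 0) stop("cannot embed two axes", call. = FALSE)
  if (angle == 0) return(u)
  repeat {
    w <- stats::rnorm(n)
    w <- w - sum(w * u) * u
    nw <- sqrt(sum(w^2))
    if (nw > 1e-8) break
  }
  w <- w / nw
  cos(angle) * u + sin(angle) * w
}

#' Count events per half-open interval [start, end)
#'
#' `times` must be sorted nondecreasing. findInterval(x, times,
#' left.open = TRUE) counts times strictly below x, so the difference counts
#' start <= t < end.
#' @noRd
count_in_intervals <- function(times, starts, ends) {
  findInterval(ends, times, left.open = TRUE) -
    findInterval(starts, times, left.open = TRUE)
}

#' Round times to the 0.1 ms recording grid (half-even, as base round())
#' @noRd
round_time <- function(x) round(x, 4)
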