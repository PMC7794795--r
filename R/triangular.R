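#' Triangular distribution
#'
#' The triangular distribution is the standard way bounded, sparsely
#' characterised exposure parameters are represented in probabilistic risk
#' assessment: a minimum, a "likeliest" central value (the mode), and a
#' maximum. Here the mode slot typically carries an observed cohort *median*
#' used as a stand-in for the likeliest value, which is how field summaries
#' of the form (min, median, max) are turned into a sampling distribution.
#'
#' @param minimum Lower bound of the support.
#' @param likeliest Mode of the distribution; must lie in
#'   `[minimum, maximum]`. When built from a data summary this is the
#'   sample median standing in for the mode.
#' @param maximum Upper bound of the support; must exceed `minimum`.
#'
#' @return An object of class `"triangular"` with fields `minimum`,
#'   `likeliest`, `maximum`.
#' @examples
#' d <- triangular(19.2, 34.8, 82.4) # child body weight, kg
#' mean(rtriangular(1000, d))
#' @export
triangular <- function(minimum, likeliest, maximum) {
  for (v in list(minimum, likeliest, maximum)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("triangular parameters must be finite numeric scalars", call. = FALSE)
    }
  }
  if (minimum > likeliest || likeliest > maximum) {
    stop(sprintf(
      "triangular distribution requires minimum <= likeliest <= maximum (got %g, %g, %g)",
      minimum, likeliest, maximum
    ), call. = FALSE)
  }
  if (minimum == maximum) {
    stop("degenerate triangular distribution: minimum equals maximum", call. = FALSE)
  }
  structure(
    list(minimum = minimum, likeliest = likeliest, maximum = maximum),
    class = "triangular"
  )
}

#' @export
print.triangular <- function(x, ...) {
  cat(sprintf(
    "triangular(minimum = %g, likeliest = %g, maximum = %g)\n",
    x$minimum, x$likeliest, x$maximum
  ))
  invisible(x)
}

#' Triangular cumulative distribution function
#'
#' @param q Vector of quantiles.
#' @param dist A [triangular()] distribution.
#' @return `P(X <= q)` for each element of `q`.
#' @export
ptriangular <- function(q, dist) {
  stopifnot(inherits(dist, "triangular"))
  a <- dist$minimum
  c <- dist$likeliest
  b <- dist$maximum
  p <- numeric(length(q))
  p[q >= b] <- 1
  lo <- q > a & q <= c
  hi <- q > c & q < b
  if (c > a) p[lo] <- (q[lo] - a)^2 / ((b - a) * (c - a))
  p[hi] <- 1 - (b - q[hi])^2 / ((b - a) * (b - c))
  p
}

#' Triangular quantile function (inverse CDF)
#'
#' For `u` below the mode's CDF value `(c - a) / (b - a)` the quantile is
#' `a + sqrt(u (b - a)(c - a))`; otherwise `b - sqrt((1 - u)(b - a)(b - c))`,
#' with `a`, `c`, `b` the minimum, mode, and maximum.
#'
#' @param p Vector of probabilities in `[0, 1]`.
#' @param dist A [triangular()] distribution.
#' @return Quantiles, each inside `[minimum, maximum]`.
#' @export
qtriangular <- function(p, dist) {
  stopifnot(inherits(dist, "triangular"))
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  a <- dist$minimum
  c <- dist$likeliest
  b <- dist$maximum
  fc <- (c - a) / (b - a)
  x <- numeric(length(p))
  left <- p < fc
  x[left] <- a + sqrt(p[left] * (b - a) * (c - a))
  x[!left] <- b - sqrt((1 - p[!left]) * (b - a) * (b - c))
  x
}

#' Sample a triangular distribution by inversion
#'
#' Inverse-CDF sampling driven by R's global random-number stream, so a
#' prior `set.seed()` call makes draws fully reproducible.
#'
#' @param n Number of samples, at least 1.
#' @param dist A [triangular()] distribution.
#' @return `n` samples, all inside `[minimum, maximum]`.
#' @export
rtriangular <- function(n, dist) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  qtriangular(stats::runif(n), dist)
}
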