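#' Monte Carlo simulation specification
#'
#' Bundles everything one uncertainty run needs: the triangular
#' distributions for the sampled parameters, the fixed exposure profile
#' supplying every non-sampled parameter, the chemical toxicity constants,
#' the iteration count, and the seed. Sampled parameters are restricted to
#' body weight, skin surface area, visit frequency, and medium
#' concentration; a `concentration` distribution is required because the
#' per-iteration risk is the risk from one sampled single-medium
#' concentration, not a sum over media.
#'
#' @param distributions Named list of [triangular()] distributions; names
#'   from `{body_weight, skin_surface_area, frequency, concentration}` and
#'   `concentration` must be present.
#' @param profile An [exposure_profile()] supplying fixed parameters.
#' @param tox A [chemical_toxicity()].
#' @param iterations Number of Monte Carlo iterations, default 1000.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(distributions, profile, tox,
                            iterations = 1000L, seed = 1L) {
  stopifnot(inherits(profile, "exposure_profile"), inherits(tox, "chemical_toxicity"))
  allowed <- c("body_weight", "skin_surface_area", "frequency", "concentration")
  if (!is.list(distributions) || is.null(names(distributions)) ||
      !all(names(distributions) %in% allowed)) {
    stop(sprintf("distribution names must be a subset of {%s}",
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(distributions)) {
    if (!inherits(distributions[[nm]], "triangular")) {
      stop(sprintf("distribution '%s' is not a triangular distribution", nm),
           call. = FALSE)
    }
  }
  if (is.null(distributions$concentration)) {
    stop("a 'concentration' distribution is required", call. = FALSE)
  }
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1) {
    stop("'iterations' must be at least 1", call. = FALSE)
  }
  structure(
    list(
      distributions = distributions, profile = profile, tox = tox,
      iterations = as.integer(iterations), seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' Run a Monte Carlo uncertainty simulation
#'
#' For each iteration one value is drawn independently from each sampled
#' parameter's triangular distribution, the exposure profile is rebuilt
#' with the drawn values, and the oral, dermal, and inhalation risks are
#' evaluated through the deterministic risk model for the drawn
#' concentration. The exposure factor is recomputed each iteration from
#' the sampled frequency with fixed duration and averaging time (any
#' exposure-factor override on the profile is ignored when frequency is
#' sampled). Per-route results are summarised by the mean and the
#' empirical 2.5% and 97.5% quantiles.
#'
#' All iterations are evaluated in one vectorized pass; draws are taken
#' parameter-by-parameter in a fixed order (body weight, skin surface
#' area, frequency, concentration), so results are bit-identical for a
#' given spec and seed.
#'
#' @param spec A [simulation_spec()].
#' @param keep_samples Retain the iterations-by-route risk matrix in the
#'   result (default `TRUE`).
#' @return An object of class `"simulation_summary"`: `summary` is a
#'   3 x 3 matrix (routes by mean / 2.5% / 97.5%), plus `iterations`,
#'   `seed`, and optionally `samples`.
#' @export
run_simulation <- function(spec, keep_samples = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$iterations
  d <- spec$distributions
  prof <- spec$profile

  draw <- function(key, fixed) {
    if (is.null(d[[key]])) rep_len(fixed, n) else rtriangular(n, d[[key]])
  }
  bw <- draw("body_weight", prof$body_weight)
  sa <- draw("skin_surface_area", prof$skin_surface_area)
  fr <- draw("frequency", prof$frequency)
  conc <- rtriangular(n, d$concentration)

  prof$body_weight <- bw
  prof$skin_surface_area <- sa
  prof$frequency <- fr
  if (!is.null(d$frequency)) prof$exposure_factor_override <- NULL

  risks <- cbind(
    oral = route_risk(dose_oral(conc, prof, spec$tox), spec$tox$slope_oral),
    dermal = route_risk(dose_dermal(conc, prof, spec$tox), spec$tox$slope_dermal),
    inhalation = route_risk(dose_inhalation(conc, prof, spec$tox),
                            spec$tox$slope_inhalation)
  )

  summ <- t(apply(risks, 2, function(s) {
    c(mean(s), summarize_samples(s, c(0.025, 0.975)))
  }))
  dimnames(summ) <- list(colnames(risks), c("mean", "2.5%", "97.5%"))

  structure(
    list(
      summary = summ, iterations = n, seed = spec$seed,
      samples = if (keep_samples) risks else NULL
    ),
    class = "simulation_summary"
  )
}

#' Empirical quantiles of simulated risks
#'
#' Quantiles are taken by linear interpolation between order statistics
#' (the convention where the k-th of n sorted values sits at probability
#' `(k - 1) / (n - 1)`; `stats::quantile()` type 7). The convention is
#' stated because spreadsheet Monte Carlo tools differ in theirs.
#'
#' @param samples Non-empty numeric vector of per-iteration results.
#' @param probabilities Probabilities in `[0, 1]`.
#' @return Named vector of empirical quantiles, monotone in probability.
#' @examples
#' summarize_samples(c(1, 2, 3, 4, 5), 0.5)
#' @export
summarize_samples <- function(samples, probabilities) {
  if (length(samples) == 0L) stop("'samples' must be non-empty", call. = FALSE)
  if (any(!is.finite(samples))) stop("'samples' must be finite", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::quantile(samples, probs = probabilities, type = 7, names = FALSE)
  stats::setNames(q, sprintf("%g%%", 100 * probabilities))
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(render_simulation_report(x, ...))
  invisible(x)
}
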