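#' Default triangular distributions for the beach child cohort
#'
#' The (minimum, likeliest, maximum) triples describing the observed child
#' cohort and the contaminated-media chemical data: body weight (kg), skin
#' surface area (cm2), beach-visit frequency (days/year), and
#' benzo[b]fluoranthene concentration (mg/kg, spanning sediment through
#' weathered oil). The likeliest values are cohort medians standing in for
#' the triangular mode.
#'
#' @return Named list of [triangular()] distributions with entries
#'   `body_weight`, `skin_surface_area`, `frequency`, `concentration`.
#' @export
beaches_distributions <- function() {
  list(
    body_weight = triangular(19.2, 34.8, 82.4),
    skin_surface_area = triangular(7430, 12582, 21258),
    frequency = triangular(1, 3, 50),
    concentration = triangular(0.62, 1.46, 4.40)
  )
}

#' Generate a synthetic child cohort
#'
#' Draws per-child body weight, skin surface area, and annual beach-visit
#' frequency independently from triangular distributions, emulating the
#' statistical structure of a field survey of children playing on a beach.
#' Frequency is rounded to the nearest whole number of visits and floored
#' at 1 (an observed child visited at least once). Body weight and skin
#' surface area are sampled independently although physically correlated;
#' the downstream analysis assumes independence, so the generator does
#' too.
#'
#' @param n Number of children, at least 1.
#' @param distributions Named list of [triangular()] distributions with
#'   entries `body_weight`, `skin_surface_area`, `frequency`; defaults to
#'   the observed-cohort triples of [beaches_distributions()].
#' @param seed Optional integer seed; when supplied, `set.seed()` is
#'   called so the cohort is reproducible.
#' @return A data.frame with columns `child_id`, `body_weight` (kg),
#'   `skin_surface_area` (cm2), `beach_frequency` (integer days/year).
#' @examples
#' cohort <- generate_cohort(122, seed = 7)
#' summarize_cohort(cohort)
#' @export
generate_cohort <- function(n, distributions = beaches_distributions(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  for (nm in c("body_weight", "skin_surface_area", "frequency")) {
    if (!inherits(distributions[[nm]], "triangular")) {
      stop(sprintf("invalid or missing triangular distribution for '%s'", nm),
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  data.frame(
    child_id = sprintf("child_%05d", seq_len(n)),
    body_weight = rtriangular(n, distributions$body_weight),
    skin_surface_area = rtriangular(n, distributions$skin_surface_area),
    beach_frequency = pmax(1, round(rtriangular(n, distributions$frequency)))
  )
}

cohort_parameters <- c("body_weight", "skin_surface_area", "beach_frequency")

#' Summarise a cohort into min / median / max / mean per parameter
#'
#' Distils per-child observations the way a risk assessment distils field
#' data before fitting distributions: the minimum and maximum are taken
#' from each parameter's observed range and the median is recorded as the
#' central value. The median of an even-sized cohort is the mean of the
#' two central order statistics.
#'
#' @param cohort A cohort data.frame as produced by [generate_cohort()]
#'   (columns `body_weight`, `skin_surface_area`, `beach_frequency`).
#' @return A data.frame of class `"cohort_summary"` with one row per
#'   parameter and columns `parameter`, `minimum`, `median`, `maximum`,
#'   `mean`, `n`.
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("'cohort' must be a non-empty data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(cohort_parameters, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(cohort_parameters, function(p) {
    v <- cohort[[p]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("cohort column '%s' must be positive and finite", p),
           call. = FALSE)
    }
    data.frame(
      parameter = p, minimum = min(v), median = stats::median(v),
      maximum = max(v), mean = mean(v), n = length(v)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Turn cohort summaries into triangular distributions
#'
#' Applies the plug-in rule used to build sampling distributions from
#' field summaries: `triangular(minimum, median, maximum)`, with the
#' sample median standing in for the likeliest value (the mode). This is
#' deliberately not a maximum-likelihood fit. The `beach_frequency`
#' parameter is renamed `frequency` so the result plugs straight into
#' [simulation_spec()].
#'
#' @param summary A `"cohort_summary"` from [summarize_cohort()].
#' @return Named list of [triangular()] distributions, one per parameter.
#' @export
fit_triangular <- function(summary) {
  if (!inherits(summary, "cohort_summary")) {
    stop("'summary' must be a cohort_summary", call. = FALSE)
  }
  fits <- lapply(seq_len(nrow(summary)), function(i) {
    row <- summary[i, ]
    if (row$minimum == row$maximum) {
      stop(sprintf("degenerate distribution for '%s': minimum equals maximum",
                   row$parameter), call. = FALSE)
    }
    triangular(row$minimum, row$median, row$maximum)
  })
  nms <- sub("^beach_frequency$", "frequency", summary$parameter)
  stats::setNames(fits, nms)
}

# File header used for cohort interchange; maps internal column names to
# explicit unit-bearing names.
cohort_file_columns <- c(
  child_id = "child_id",
  body_weight = "body_weight_kg",
  skin_surface_area = "skin_surface_area_cm2",
  beach_frequency = "beach_frequency_days_per_year"
)

#' Write / read a cohort as a tab-separated table
#'
#' The on-disk header carries units
#' (`child_id`, `body_weight_kg`, `skin_surface_area_cm2`,
#' `beach_frequency_days_per_year`); in-memory columns use the bare names.
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), all(names(cohort_file_columns) %in% names(cohort)))
  out <- cohort[, names(cohort_file_columns)]
  names(out) <- unname(cohort_file_columns)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(cohort_file_columns), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("cohort file is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- raw[, unname(cohort_file_columns)]
  names(out) <- names(cohort_file_columns)
  out
}
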