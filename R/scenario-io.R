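#' Path to a bundled scenario file
#'
#' @param name Scenario name; bundled scenarios are `"beaches"` (exposure
#'   parameters averaged from an observed child cohort) and
#'   `"literature-default"` (default exposure parameters from the
#'   published literature).
#' @return Path to the installed YAML scenario file.
#' @export
scenario_path <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "beachrisk")
  if (!nzchar(path)) {
    stop(sprintf("no bundled scenario named '%s'", name), call. = FALSE)
  }
  path
}

scenario_field <- function(section, section_name, field, optional = FALSE) {
  v <- section[[field]]
  if (is.null(v)) {
    if (optional) return(NULL)
    stop(sprintf("scenario field '%s.%s' is missing", section_name, field),
         call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(v))
  if (length(num) != 1L || is.na(num)) {
    stop(sprintf("scenario field '%s.%s' is not a number (got '%s')",
                 section_name, field, paste(v, collapse = " ")), call. = FALSE)
  }
  num
}

#' Load and validate a scenario configuration
#'
#' A scenario is a YAML file with sections `chemical` (toxicity
#' constants), `concentrations` (per-medium chemical concentrations in
#' mg/kg), `exposure` (the population exposure-parameter set), and an
#' optional `distributions` section of per-parameter
#' minimum/likeliest/maximum triples for Monte Carlo runs. Every nested
#' invariant (fractions in range, positive parameters, ordered triangular
#' triples) is enforced at load time with field-level error messages.
#'
#' @param path Path to a scenario file, or the bare name of a bundled
#'   scenario (see [scenario_path()]).
#' @return An object of class `"scenario"`: `name`, `tox`
#'   ([chemical_toxicity()]), `media` (named concentration vector),
#'   `profile` ([exposure_profile()]), and `distributions` (named list of
#'   [triangular()], or `NULL`).
#' @examples
#' sc <- load_scenario("beaches")
#' risk_table(sc$media, sc$profile, sc$tox)
#' @export
load_scenario <- function(path) {
  file <- if (file.exists(path)) path else scenario_path(path)
  raw <- yaml::read_yaml(file)

  section <- function(name, optional = FALSE) {
    s <- raw[[name]]
    if (is.null(s) && !optional) {
      stop(sprintf("scenario file is missing the '%s' section", name),
           call. = FALSE)
    }
    s
  }

  name <- raw$name
  if (is.null(name) || !nzchar(name)) {
    stop("scenario field 'name' is missing or empty", call. = FALSE)
  }

  chem <- section("chemical")
  if (is.null(chem$name)) stop("scenario field 'chemical.name' is missing", call. = FALSE)
  tox <- chemical_toxicity(
    name = as.character(chem$name),
    rba_oral = scenario_field(chem, "chemical", "rba_oral"),
    slope_oral = scenario_field(chem, "chemical", "slope_oral"),
    abs_dermal = scenario_field(chem, "chemical", "abs_dermal"),
    slope_dermal = scenario_field(chem, "chemical", "slope_dermal"),
    slope_inhalation = scenario_field(chem, "chemical", "slope_inhalation")
  )

  conc <- section("concentrations")
  if (!is.list(conc) || length(conc) == 0L || is.null(names(conc))) {
    stop("'concentrations' must map medium labels to mg/kg values", call. = FALSE)
  }
  media <- vapply(names(conc), function(m) {
    scenario_field(conc, "concentrations", m)
  }, numeric(1))

  exp <- section("exposure")
  profile <- exposure_profile(
    body_weight = scenario_field(exp, "exposure", "body_weight"),
    frequency = scenario_field(exp, "exposure", "frequency"),
    duration = scenario_field(exp, "exposure", "duration"),
    averaging_time = scenario_field(exp, "exposure", "averaging_time"),
    intake_rate_soil = scenario_field(exp, "exposure", "intake_rate_soil"),
    conversion_factor = scenario_field(exp, "exposure", "conversion_factor"),
    skin_surface_area = scenario_field(exp, "exposure", "skin_surface_area"),
    adherence_factor = scenario_field(exp, "exposure", "adherence_factor"),
    particulate_emission_factor = scenario_field(exp, "exposure", "particulate_emission_factor"),
    inhalation_rate = scenario_field(exp, "exposure", "inhalation_rate"),
    exposure_time = scenario_field(exp, "exposure", "exposure_time"),
    exposure_factor_override = scenario_field(exp, "exposure", "exposure_factor_override",
                                              optional = TRUE)
  )

  dists <- section("distributions", optional = TRUE)
  distributions <- NULL
  if (!is.null(dists)) {
    distributions <- lapply(names(dists), function(p) {
      d <- dists[[p]]
      triangular(
        scenario_field(d, paste0("distributions.", p), "minimum"),
        scenario_field(d, paste0("distributions.", p), "likeliest"),
        scenario_field(d, paste0("distributions.", p), "maximum")
      )
    })
    names(distributions) <- names(dists)
  }

  structure(
    list(name = name, tox = tox, media = media, profile = profile,
         distributions = distributions),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %s in %d media (%s)\n", x$name, x$tox$name,
              length(x$media), paste(names(x$media), collapse = ", ")))
  if (!is.null(x$distributions)) {
    cat(sprintf("  distributions for: %s\n",
                paste(names(x$distributions), collapse = ", ")))
  }
  invisible(x)
}

format_risk <- function(x, raw = FALSE) {
  if (raw) sprintf("%.15g", x) else formatC(x, format = "e", digits = 2)
}

#' Render a point-risk table as a tab-separated report
#'
#' One row per medium, one column per route, plus a `total` row and
#' column. Values use scientific notation at 3 significant figures (the
#' usual display precision for risk estimates) unless `raw = TRUE`, which
#' prints full double precision. Rendering is deterministic:
#' byte-identical output for equal tables.
#'
#' @param table A [risk_table()].
#' @param raw Print full-precision values instead of 3 significant figures.
#' @return The report as a single character string.
#' @export
render_point_report <- function(table, raw = FALSE) {
  stopifnot(inherits(table, "risk_table"))
  routes <- colnames(table$cells)
  header <- paste(c("medium", routes, "total"), collapse = "\t")
  body <- vapply(rownames(table$cells), function(m) {
    paste(c(m, format_risk(c(table$cells[m, ], table$medium_totals[[m]]), raw)),
          collapse = "\t")
  }, character(1))
  total <- paste(c("total", format_risk(c(table$route_totals, table$grand_total), raw)),
                 collapse = "\t")
  paste0(
    sprintf("# lifetime excess cancer risk: %s\n", table$chemical),
    paste(c(header, body, total), collapse = "\n"), "\n"
  )
}

#' Render a Monte Carlo summary as a tab-separated report
#'
#' One row per exposure route with the mean and the empirical 2.5% and
#' 97.5% quantiles of the simulated risks, in 3-significant-figure
#' scientific notation (or full precision with `raw = TRUE`).
#'
#' @param summary A `"simulation_summary"` from [run_simulation()].
#' @param raw Print full-precision values.
#' @return The report as a single character string.
#' @export
render_simulation_report <- function(summary, raw = FALSE) {
  stopifnot(inherits(summary, "simulation_summary"))
  header <- paste(c("route", colnames(summary$summary)), collapse = "\t")
  body <- vapply(rownames(summary$summary), function(r) {
    paste(c(r, format_risk(summary$summary[r, ], raw)), collapse = "\t")
  }, character(1))
  paste0(
    sprintf("# Monte Carlo cancer risk summary (%d iterations, seed %d)\n",
            summary$iterations, summary$seed),
    paste(c(header, body), collapse = "\n"), "\n"
  )
}
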