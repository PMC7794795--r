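#' Chemical toxicity constants
#'
#' Route-specific toxicity inputs for one carcinogen: cancer slope factors
#' (excess lifetime risk per mg/(kg day) of chronic dose) for the oral,
#' dermal, and inhalation routes, plus the oral relative bioavailability
#' (RBA, the fraction of ingested soil-bound chemical absorbed relative to
#' the toxicity study's dosing vehicle) and the dermal absorption fraction
#' (ABS, fraction of chemical in skin-adhered soil absorbed per event).
#'
#' @param name Chemical name.
#' @param rba_oral Oral relative bioavailability, a fraction in `[0, 1]`.
#' @param slope_oral Oral cancer slope factor, per mg/(kg day).
#' @param abs_dermal Dermal absorption fraction in `[0, 1]`.
#' @param slope_dermal Dermal cancer slope factor, per mg/(kg day).
#' @param slope_inhalation Inhalation cancer slope factor, per mg/(kg day).
#' @return An object of class `"chemical_toxicity"`.
#' @examples
#' chemical_toxicity("benzo[b]fluoranthene", 0.5, 0.73, 0.01, 1.46, 0.31)
#' @export
chemical_toxicity <- function(name, rba_oral, slope_oral, abs_dermal,
                              slope_dermal, slope_inhalation) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("chemical name must be a non-empty string", call. = FALSE)
  }
  vals <- list(
    rba_oral = rba_oral, slope_oral = slope_oral, abs_dermal = abs_dermal,
    slope_dermal = slope_dermal, slope_inhalation = slope_inhalation
  )
  for (f in names(vals)) {
    v <- vals[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a non-negative finite number", f), call. = FALSE)
    }
  }
  if (rba_oral > 1) stop("'rba_oral' is a fraction and cannot exceed 1", call. = FALSE)
  if (abs_dermal > 1) stop("'abs_dermal' is a fraction and cannot exceed 1", call. = FALSE)
  structure(c(list(name = name), vals), class = "chemical_toxicity")
}

#' Population exposure profile
#'
#' All non-sampled exposure parameters for one receptor population. Units
#' follow the conventional dose equations for incidental soil contact:
#' body weight in kg, visit frequency in days/year, exposure duration in
#' years, averaging time in days (a lifetime averaging time for cancer
#' endpoints), soil intake in mg/day, skin surface area in cm2/event, soil
#' adherence in mg/cm2, particulate emission factor in m3/kg, inhalation
#' rate in m3/day, and exposure time in hours/day.
#'
#' `conversion_factor` is the mg-to-kg mass conversion (nominally 1e-6)
#' applied exactly once in the oral and dermal dose equations; the
#' inhalation equation carries no such term.
#'
#' `exposure_factor_override`, when supplied, replaces the exposure factor
#' computed by [exposure_factor()] from `frequency`, `duration` and
#' `averaging_time`. This exists so a scenario can reproduce a published
#' exposure factor that is not consistent with its own printed frequency
#' and duration.
#'
#' Zero `frequency` or `exposure_time` is a valid "no exposure" input and
#' yields zero risk downstream; zero body weight, averaging time, or
#' particulate emission factor is an error.
#'
#' Fields may be vectors of a common length (or length 1), which is how
#' the Monte Carlo engine evaluates all iterations in one vectorized pass.
#'
#' @param body_weight Body weight BW, kg.
#' @param frequency Exposure frequency F, days/year (>= 0).
#' @param duration Exposure duration ED, years.
#' @param averaging_time Averaging time AT, days.
#' @param intake_rate_soil Soil intake rate IRs, mg/day.
#' @param conversion_factor Mass conversion CF, default `1e-6`.
#' @param skin_surface_area Skin surface area SA, cm2/event.
#' @param adherence_factor Soil-to-skin adherence AF, mg/cm2.
#' @param particulate_emission_factor Soil-to-air particulate emission
#'   factor PEF, m3/kg.
#' @param inhalation_rate Inhalation rate IRa, m3/day.
#' @param exposure_time Exposure time ET, hours/day (>= 0).
#' @param exposure_factor_override Optional unitless exposure factor EF in
#'   (0, 1) that wins over the computed F x ED / AT.
#' @return An object of class `"exposure_profile"`.
#' @export
exposure_profile <- function(body_weight, frequency, duration, averaging_time,
                             intake_rate_soil, conversion_factor = 1e-6,
                             skin_surface_area, adherence_factor,
                             particulate_emission_factor, inhalation_rate,
                             exposure_time, exposure_factor_override = NULL) {
  positive <- list(
    body_weight = body_weight, duration = duration,
    averaging_time = averaging_time, intake_rate_soil = intake_rate_soil,
    conversion_factor = conversion_factor,
    skin_surface_area = skin_surface_area,
    adherence_factor = adherence_factor,
    particulate_emission_factor = particulate_emission_factor,
    inhalation_rate = inhalation_rate
  )
  for (f in names(positive)) {
    v <- positive[[f]]
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be strictly positive", f), call. = FALSE)
    }
  }
  for (f in c("frequency", "exposure_time")) {
    v <- list(frequency = frequency, exposure_time = exposure_time)[[f]]
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("'%s' must be non-negative", f), call. = FALSE)
    }
  }
  if (!is.null(exposure_factor_override)) {
    ef <- exposure_factor_override
    if (!is.numeric(ef) || any(ef <= 0) || any(ef >= 1)) {
      stop("'exposure_factor_override' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (any(duration * frequency > averaging_time)) {
    stop("duration x frequency exceeds averaging_time: more exposure days than averaged days",
         call. = FALSE)
  }
  structure(
    list(
      body_weight = body_weight, frequency = frequency, duration = duration,
      averaging_time = averaging_time, intake_rate_soil = intake_rate_soil,
      conversion_factor = conversion_factor,
      skin_surface_area = skin_surface_area,
      adherence_factor = adherence_factor,
      particulate_emission_factor = particulate_emission_factor,
      inhalation_rate = inhalation_rate, exposure_time = exposure_time,
      exposure_factor_override = exposure_factor_override
    ),
    class = "exposure_profile"
  )
}

#' Exposure factor
#'
#' The unitless fraction of the averaging time during which exposure
#' occurs: `EF = F x ED / AT` with F the frequency (days/year), ED the
#' duration (years), and AT the averaging time (days). For cancer
#' endpoints AT is a lifetime expressed in days.
#'
#' @param frequency Days/year of exposure (>= 0; 0 means no exposure).
#' @param duration Exposure duration in years (> 0).
#' @param averaging_time Averaging time in days (> 0).
#' @return The dimensionless exposure factor. Vectorized.
#' @examples
#' exposure_factor(3, 8, 28489)  # ~0.000842, lifetime averaging
#' exposure_factor(3, 8, 365)    # ~0.0658, single-year averaging
#' @export
exposure_factor <- function(frequency, duration, averaging_time) {
  if (any(frequency < 0)) stop("'frequency' must be non-negative", call. = FALSE)
  if (any(duration <= 0)) stop("'duration' must be strictly positive", call. = FALSE)
  if (any(averaging_time <= 0)) {
    stop("'averaging_time' must be strictly positive", call. = FALSE)
  }
  frequency * duration / averaging_time
}

# Exposure factor for a profile: the override wins when present, else
# computed from F, ED, AT.
profile_exposure_factor <- function(profile) {
  if (!is.null(profile$exposure_factor_override)) {
    profile$exposure_factor_override
  } else {
    exposure_factor(profile$frequency, profile$duration, profile$averaging_time)
  }
}

check_concentration <- function(concentration) {
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    stop("'concentration' must be non-negative and finite", call. = FALSE)
  }
}

#' Average daily dose from incidental soil ingestion
#'
#' `Dose = C x IRs x RBA x EF x CF / BW`, in mg/(kg day): medium
#' concentration times soil intake rate, discounted by oral relative
#' bioavailability, scaled by the exposure factor and the mg-to-kg
#' conversion, and normalised to body weight.
#'
#' @param concentration Chemical concentration C in the medium, mg/kg.
#' @param profile An [exposure_profile()].
#' @param tox A [chemical_toxicity()].
#' @return Dose in mg/(kg day). Vectorized over `concentration` and over
#'   vector-valued profile fields.
#' @seealso [dose_dermal()], [dose_inhalation()], [route_risk()]
#' @export
dose_oral <- function(concentration, profile, tox) {
  stopifnot(inherits(profile, "exposure_profile"), inherits(tox, "chemical_toxicity"))
  check_concentration(concentration)
  ef <- profile_exposure_factor(profile)
  concentration * profile$intake_rate_soil * tox$rba_oral * ef *
    profile$conversion_factor / profile$body_weight
}

#' Average daily dose from dermal contact
#'
#' `Dose = C x SA x AF x ABS x EF x CF / BW`, in mg/(kg day): chemical in
#' the soil load adhering to exposed skin (surface area times adherence),
#' discounted by the per-event dermal absorption fraction. A single soil
#' loading event per exposure day is assumed; repeated wash-and-reload
#' cycles during a visit are not modelled.
#'
#' @inheritParams dose_oral
#' @return Dose in mg/(kg day).
#' @export
dose_dermal <- function(concentration, profile, tox) {
  stopifnot(inherits(profile, "exposure_profile"), inherits(tox, "chemical_toxicity"))
  check_concentration(concentration)
  ef <- profile_exposure_factor(profile)
  concentration * profile$skin_surface_area * profile$adherence_factor *
    tox$abs_dermal * ef * profile$conversion_factor / profile$body_weight
}

#' Average daily dose from inhaling suspended particulates
#'
#' `Dose = C x (1 / PEF) x IRa x ET x EF / BW`, in mg/(kg day): the
#' soil-to-air particulate emission factor converts the solid-phase soil
#' concentration into an airborne particulate concentration, which is
#' scaled by the inhalation rate and the daily exposure time. No gas-phase
#' exposure is represented. The exposure time ET (hours/day) enters as a
#' bare multiplier, with no /24 normalisation, matching the published form
#' of the equation this implements; see the methods vignette for the
#' dimensional caveat. No mass conversion factor appears in this route.
#'
#' @inheritParams dose_oral
#' @return Dose in mg/(kg day).
#' @export
dose_inhalation <- function(concentration, profile, tox) {
  stopifnot(inherits(profile, "exposure_profile"), inherits(tox, "chemical_toxicity"))
  check_concentration(concentration)
  ef <- profile_exposure_factor(profile)
  concentration * (1 / profile$particulate_emission_factor) *
    profile$inhalation_rate * profile$exposure_time * ef / profile$body_weight
}

#' Lifetime excess cancer risk from a chronic dose
#'
#' `Risk = Dose x Slope factor`: the linear low-dose extrapolation used
#' for carcinogens, with the route-specific slope factor an upper-bound
#' estimate of excess lifetime cancer risk per unit chronic daily dose.
#' Risks are not clamped to `[0, 1]`; the linear model is only credible
#' for small risks, so a warning is emitted whenever a computed risk
#' exceeds 0.01.
#'
#' @param dose Average daily dose, mg/(kg day), non-negative.
#' @param slope_factor Cancer slope factor, per mg/(kg day), non-negative.
#' @return Unitless lifetime excess cancer risk. Vectorized.
#' @examples
#' route_risk(5.32e-8, 0.73)
#' @export
route_risk <- function(dose, slope_factor) {
  if (any(dose < 0)) stop("'dose' must be non-negative", call. = FALSE)
  if (any(slope_factor < 0)) stop("'slope_factor' must be non-negative", call. = FALSE)
  risk <- dose * slope_factor
  if (any(risk > 0.01)) {
    warning("computed risk exceeds 0.01; the linear low-dose model is not credible at this level",
            call. = FALSE)
  }
  risk
}

normalize_media <- function(media) {
  if (is.data.frame(media)) {
    if (!all(c("medium", "concentration") %in% names(media))) {
      stop("media data.frame needs 'medium' and 'concentration' columns", call. = FALSE)
    }
    media <- stats::setNames(media$concentration, as.character(media$medium))
  }
  if (!is.numeric(media) || length(media) == 0L) {
    stop("media must be a non-empty named numeric vector of concentrations (mg/kg)",
         call. = FALSE)
  }
  if (is.null(names(media)) || any(!nzchar(names(media)))) {
    stop("every medium concentration must be named", call. = FALSE)
  }
  if (anyDuplicated(names(media))) {
    stop(sprintf("duplicate medium labels: %s",
                 paste(unique(names(media)[duplicated(names(media))]), collapse = ", ")),
         call. = FALSE)
  }
  check_concentration(media)
  media
}

#' Point-risk table across media and exposure routes
#'
#' Evaluates the oral, dermal, and inhalation risk for each contaminated
#' medium (e.g. sediment, weathered oil, tar) under one exposure profile
#' and one chemical, and aggregates: per-route totals, per-medium totals,
#' and the grand total. Route doses are additive across media for a
#' receptor contacting all media, so totals are plain sums of cells.
#'
#' @param media Named numeric vector of concentrations in mg/kg (names are
#'   medium labels), or a data.frame with `medium` and `concentration`
#'   columns. Labels must be unique.
#' @param profile An [exposure_profile()] with scalar fields.
#' @param tox A [chemical_toxicity()].
#' @return An object of class `"risk_table"` with fields `cells` (media x
#'   route matrix), `route_totals`, `medium_totals`, `grand_total`,
#'   `chemical`, and `concentrations`.
#' @examples
#' tox <- chemical_toxicity("benzo[b]fluoranthene", 0.5, 0.73, 0.01, 1.46, 0.31)
#' prof <- exposure_profile(
#'   body_weight = 34.8, frequency = 3, duration = 8, averaging_time = 28489,
#'   intake_rate_soil = 1000, skin_surface_area = 12582, adherence_factor = 18,
#'   particulate_emission_factor = 1.24e9, inhalation_rate = 9.62,
#'   exposure_time = 3
#' )
#' risk_table(c(sediment = 1.46, weathered_oil = 4.40, tar = 0.62), prof, tox)
#' @export
risk_table <- function(media, profile, tox) {
  media <- normalize_media(media)
  cells <- cbind(
    oral = route_risk(dose_oral(media, profile, tox), tox$slope_oral),
    dermal = route_risk(dose_dermal(media, profile, tox), tox$slope_dermal),
    inhalation = route_risk(dose_inhalation(media, profile, tox), tox$slope_inhalation)
  )
  rownames(cells) <- names(media)
  structure(
    list(
      cells = cells,
      route_totals = colSums(cells),
      medium_totals = rowSums(cells),
      grand_total = sum(cells),
      chemical = tox$name,
      concentrations = media
    ),
    class = "risk_table"
  )
}

#' @export
print.risk_table <- function(x, ...) {
  cat(render_point_report(x, ...))
  invisible(x)
}
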