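# Scenario: exposure parameters averaged from an observed cohort of 122
# children (ages 0-6) playing on Gulf-coast beaches, combined with
# default chemical-side constants shared with the literature-default
# scenario. Chemical: benzo[b]fluoranthene, a PAH measured in shoreline
# media after a major oil spill.
name: beaches

chemical:
  name: benzo[b]fluoranthene
  rba_oral: 0.5          # oral relative bioavailability (fraction)
  slope_oral: 0.73       # oral cancer slope factor, per mg/(kg day)
  abs_dermal: 0.01       # dermal absorption fraction per event
  slope_dermal: 1.46     # dermal cancer slope factor, per mg/(kg day)
  slope_inhalation: 0.31 # inhalation cancer slope factor, per mg/(kg day)

# Per-medium benzo[b]fluoranthene concentrations (mg/kg) from shoreline
# sampling. The medium mapping is back-derived from the published
# per-medium risk cells: the survey's distribution triple reports only
# min 0.62 / likeliest 1.46 / max 4.40, with weathered oil described as
# the upper limit of what sediment can carry; the point risks identify
# sediment with the central value and tar with the minimum.
concentrations:
  sediment: 1.46
  weathered_oil: 4.40
  tar: 0.62

exposure:
  body_weight: 34.8          # kg, cohort average
  frequency: 3               # beach visits, days/year, cohort average
  duration: 8                # exposure duration, years
  averaging_time: 28489      # days (78-year lifetime, cancer endpoint)
  intake_rate_soil: 1000     # incidental soil ingestion, mg/day
  conversion_factor: 0.000001 # mg -> kg mass conversion
  skin_surface_area: 12582   # cm2/event, cohort average
  adherence_factor: 18       # soil adherence to skin, mg/cm2
  particulate_emission_factor: 1240000000 # m3/kg, soil-to-air
  inhalation_rate: 9.62      # m3/day
  exposure_time: 3           # hours/day at the beach

# Monte Carlo inputs: triangular min / likeliest / max triples. The
# likeliest values are cohort medians standing in for the mode. The
# concentration triple spans all three media (tar .. weathered oil).
distributions:
  body_weight:
    minimum: 19.2
    likeliest: 34.8
    maximum: 82.4
  skin_surface_area:
    minimum: 7430
    likeliest: 12582
    maximum: 21258
  frequency:
    minimum: 1
    likeliest: 3
    maximum: 50
  concentration:
    minimum: 0.62
    likeliest: 1.46
    maximum: 4.40
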