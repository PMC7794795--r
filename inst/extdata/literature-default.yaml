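# Scenario: the comparison parameter set built from default children's
# exposure factors in the published literature (ages 2-10), rather than
# from field observation. Chemical-side constants and media are shared
# with the "beaches" scenario.
#
# The exposure factor is carried verbatim as an override (0.002948)
# because the published value is not consistent with the published
# frequency and duration (12 x 8 / 28489 = 0.00337): the source computed
# it from inputs it did not print. The override reproduces the published
# risks instead of silently correcting them.
name: literature-default

chemical:
  name: benzo[b]fluoranthene
  rba_oral: 0.5
  slope_oral: 0.73
  abs_dermal: 0.01
  slope_dermal: 1.46
  slope_inhalation: 0.31

concentrations:
  sediment: 1.46
  weathered_oil: 4.40
  tar: 0.62

exposure:
  body_weight: 25.4          # kg, literature default for children
  frequency: 12              # beach visits, days/year
  duration: 8                # years
  averaging_time: 28489      # days (lifetime, cancer endpoint)
  intake_rate_soil: 1000     # mg/day
  conversion_factor: 0.000001
  skin_surface_area: 11350   # cm2/event
  adherence_factor: 18       # mg/cm2
  particulate_emission_factor: 1240000000 # m3/kg
  inhalation_rate: 9.62      # m3/day
  exposure_time: 3           # hours/day
  exposure_factor_override: 0.002948 # published cancer EF, see header
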