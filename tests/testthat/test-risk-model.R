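test_that("exposure factor is the fraction of averaging time exposed", {
  expect_equal(signif(exposure_factor(3, 8, 28489), 3), 0.000842)
  expect_equal(signif(exposure_factor(3, 8, 365), 3), 0.0658)
  expect_identical(exposure_factor(0, 8, 28489), 0)

  # F is recoverable from EF (consistency of the defining ratio)
  set.seed(5)
  for (i in 1:25) {
    f <- runif(1, 0.5, 60); ed <- runif(1, 1, 30); at <- runif(1, 400, 4e4)
    ef <- exposure_factor(f, ed, at)
    expect_equal(ef * at / ed, f, tolerance = 1e-12)
  }

  expect_error(exposure_factor(-1, 8, 28489), "non-negative")
  expect_error(exposure_factor(3, 8, 0), "positive")
  expect_error(exposure_factor(3, -8, 28489), "positive")
})

test_that("constructors enforce domain invariants", {
  expect_error(chemical_toxicity("x", 1.2, 0.73, 0.01, 1.46, 0.31), "rba_oral")
  expect_error(chemical_toxicity("x", 0.5, -1, 0.01, 1.46, 0.31), "slope_oral")
  expect_error(beaches_profile(body_weight = 0), "body_weight")
  expect_error(beaches_profile(averaging_time = 0), "averaging_time")
  expect_error(beaches_profile(particulate_emission_factor = 0),
               "particulate_emission_factor")
  expect_error(beaches_profile(exposure_factor_override = 1.5), "\\(0, 1\\)")
  # zero frequency and zero exposure time are valid no-exposure inputs
  expect_s3_class(beaches_profile(frequency = 0), "exposure_profile")
  expect_s3_class(beaches_profile(exposure_time = 0), "exposure_profile")
  # more exposure days than averaged days is impossible
  expect_error(beaches_profile(frequency = 60, averaging_time = 400),
               "exceeds averaging_time")
})

test_that("route doses and risks reproduce the published point estimates", {
  tox <- bbf_tox()
  prof <- beaches_profile()

  # dose for the highest-concentration medium (hand oracle:
  # 4.40*1000*0.5*(24/28489)*1e-6/34.8 = 5.3257e-8), then every published cell
  expect_equal(signif(dose_oral(4.40, prof, tox), 3), 5.33e-8)

  cells <- published_cells()
  dose_fns <- list(oral = dose_oral, dermal = dose_dermal,
                   inhalation = dose_inhalation)
  slopes <- c(oral = tox$slope_oral, dermal = tox$slope_dermal,
              inhalation = tox$slope_inhalation)
  for (medium in rownames(cells)) {
    for (route in colnames(cells)) {
      risk <- route_risk(dose_fns[[route]](beach_media()[[medium]], prof, tox),
                         slopes[[route]])
      expect_printed_3sf(risk, cells[medium, route])
    }
  }

  # zero concentration, zero absorption, zero exposure time give zero
  expect_identical(dose_oral(0, prof, tox), 0)
  tox0 <- chemical_toxicity("x", 0.5, 0.73, 0, 1.46, 0.31)
  expect_identical(dose_dermal(1.46, prof, tox0), 0)
  expect_identical(dose_inhalation(1.46, beaches_profile(exposure_time = 0), tox), 0)
  expect_error(dose_oral(-1, prof, tox), "non-negative")
})

test_that("risk is dose times slope with no cap and a non-linearity warning", {
  expect_equal(signif(route_risk(5.323e-8, 0.73), 3), 3.89e-8)
  expect_identical(route_risk(0, 123), 0)
  expect_warning(r <- route_risk(1.0, 1.46), "not credible")
  expect_equal(r, 1.46)
  expect_error(route_risk(-1e-9, 0.73), "non-negative")
})

test_that("risk table reproduces published totals and is additive", {
  rt <- risk_table(beach_media(), beaches_profile(), bbf_tox())

  expect_printed_3sf(rt$route_totals[["oral"]], 5.73e-8)
  expect_printed_3sf(rt$route_totals[["dermal"]], 5.19e-7)
  expect_printed_3sf(rt$route_totals[["inhalation"]], 1.13e-12)
  expect_printed_3sf(rt$grand_total, 5.76e-7)

  # independent brute-force oracle: every cell as one explicit scalar
  # product, then plain sums
  ef <- 3 * 8 / 28489
  oracle <- matrix(0, 3, 3, dimnames = list(names(beach_media()),
                                            c("oral", "dermal", "inhalation")))
  for (m in names(beach_media())) {
    C <- beach_media()[[m]]
    oracle[m, "oral"] <- C * 1000 * 0.5 * ef * 1e-6 / 34.8 * 0.73
    oracle[m, "dermal"] <- C * 12582 * 18 * 0.01 * ef * 1e-6 / 34.8 * 1.46
    oracle[m, "inhalation"] <- C * (1 / 1.24e9) * 9.62 * 3 * ef / 34.8 * 0.31
  }
  expect_equal(rt$cells, oracle, tolerance = 1e-12)
  expect_equal(rt$route_totals, colSums(oracle), tolerance = 1e-9)
  expect_equal(rt$medium_totals, rowSums(oracle), tolerance = 1e-9)
  expect_equal(rt$grand_total, sum(oracle), tolerance = 1e-9)

  expect_error(risk_table(c(sediment = 1, sediment = 2), beaches_profile(), bbf_tox()),
               "duplicate")
  expect_error(risk_table(numeric(0), beaches_profile(), bbf_tox()), "non-empty")

  zero <- risk_table(c(sediment = 0, tar = 0), beaches_profile(), bbf_tox())
  expect_true(all(zero$cells == 0) && zero$grand_total == 0)
})

test_that("cells scale linearly in concentration and fall with body weight", {
  tox <- bbf_tox()
  base <- risk_table(beach_media(), beaches_profile(), tox)
  doubled <- risk_table(2 * beach_media(), beaches_profile(), tox)
  expect_identical(doubled$cells, 2 * base$cells)

  weights <- c(19.2, 25.4, 34.8, 60, 82.4)
  risks <- sapply(weights, function(bw) {
    risk_table(beach_media(), beaches_profile(body_weight = bw), tox)$cells
  })
  # strictly decreasing in body weight, cell by cell
  expect_true(all(apply(risks, 1, function(r) all(diff(r) < 0))))
})

test_that("an exposure-factor override replaces the computed ratio", {
  tox <- bbf_tox()
  lit <- literature_profile()
  rt <- risk_table(beach_media(), lit, tox)

  # oral cells with the published override, against scalar arithmetic
  oracle_oral <- beach_media() * 1000 * 0.5 * 0.002948 * 1e-6 / 25.4 * 0.73
  expect_equal(rt$cells[, "oral"], oracle_oral, tolerance = 1e-12)

  # without the override the same inputs would give F x ED / AT instead
  no_override <- exposure_profile(
    body_weight = 25.4, frequency = 12, duration = 8, averaging_time = 28489,
    intake_rate_soil = 1000, skin_surface_area = 11350, adherence_factor = 18,
    particulate_emission_factor = 1.24e9, inhalation_rate = 9.62,
    exposure_time = 3
  )
  ratio <- dose_oral(1.46, no_override, tox) / dose_oral(1.46, lit, tox)
  expect_equal(ratio, (12 * 8 / 28489) / 0.002948, tolerance = 1e-12)
})
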