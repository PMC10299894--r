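test_that("adhesion-tension line is pinned exactly at both solvent endpoints", {
  for (theta_w in c(0, 45, 66, 104, 150)) {
    line <- zisman_from_endpoints(72, theta_w, 22)
    expect_lt(abs(zisman_adhesion_tension(72, line) -
                    72 * cos(theta_w * pi / 180)), 1e-9)
    expect_lt(abs(zisman_adhesion_tension(22, line) - 22), 1e-9)
  }
})

test_that("two-endpoint line coefficients match hand arithmetic", {
  line <- zisman_from_endpoints(72, 104, 22)
  expect_equal(line$c1, -0.78837, tolerance = 1e-4)
  expect_equal(line$c0, 39.3441, tolerance = 1e-4)
  expect_equal(zisman_adhesion_tension(47, zisman_from_endpoints(72, 45, 22)),
               36.4558, tolerance = 1e-4)
  # flat line at the critical angle
  theta_wc <- critical_water_angle(72, 22)
  flat <- zisman_from_endpoints(72, theta_wc, 22)
  expect_equal(flat$c1, 0, tolerance = 1e-12)
  expect_equal(flat$c0, 22, tolerance = 1e-9)
  # fully wetting water with gamma_w = 2 * gamma_alc: identity line
  ident <- zisman_from_endpoints(44, 0, 22)
  expect_equal(ident$c1, 1)
  expect_equal(ident$c0, 0)
  expect_error(zisman_from_endpoints(50, 45, 50),
               class = "monowet_domain_error")
})

test_that("critical water angle is arccos of the tension ratio", {
  expect_equal(critical_water_angle(72, 22), 72.2084, tolerance = 1e-4)
  expect_equal(round(critical_water_angle(72, 22)), 72)
  expect_equal(critical_water_angle(40, 40), 0)
  expect_equal(critical_water_angle(72, 36), 60)
  expect_error(critical_water_angle(22, 72), class = "monowet_domain_error")
})

test_that("line slope changes sign exactly at the critical angle", {
  theta_wc <- critical_water_angle(72, 22)
  slopes <- vapply(c(45, 66, 104), function(tw) {
    zisman_from_endpoints(72, tw, 22)$c1
  }, numeric(1))
  expect_gt(slopes[1], 0)  # 45 < theta_wc: adhesion tension falls with alcohol
  expect_gt(slopes[2], 0)  # 66 < theta_wc
  expect_lt(slopes[3], 0)  # 104 > theta_wc
})

test_that("mixture tension fitting reproduces data and endpoint truths", {
  # two-point linear interpolation
  lin <- fit_mixture_tension(tibble::tibble(x = c(0, 1), gamma = c(72, 22)),
                             method = "linear")
  expect_equal(predict(lin, 0.5), 47)

  # monotone interpolant reproduces all data points exactly
  curve <- fit_mixture_tension(mixture_table_6pt)
  expect_equal(predict(curve, mixture_table_6pt$x), mixture_table_6pt$gamma)
  # and never overshoots between points
  xs <- seq(0, 1, by = 0.001)
  gs <- predict(curve, xs)
  expect_true(all(diff(gs) <= 1e-9))
  expect_true(all(gs <= 72 + 1e-9 & gs >= 22 - 1e-9))

  # parametric exponential fit recovers endpoints within 1 mN/m under noise
  mix <- make_mixture_table(shape = "exponential", n_points = 25,
                            noise_sd = 0.5, seed = 42)
  fit <- fit_mixture_tension(mix$tension, method = "exponential")
  expect_lt(abs(predict(fit, 0) - 72), 1)
  expect_lt(abs(predict(fit, 1) - 22), 1)

  expect_error(fit_mixture_tension(tibble::tibble(x = 0.5, gamma = 47),
                                   method = "linear"),
               class = "monowet_domain_error")
  expect_error(fit_mixture_tension(tibble::tibble(x = c(0, 1), gamma = c(72, 22))),
               class = "monowet_domain_error")
  expect_warning(
    fit_mixture_tension(tibble::tibble(x = c(0, 0.5, 1), gamma = c(72, 80, 22))),
    "isotonic"
  )
  expect_error(
    fit_mixture_tension(tibble::tibble(x = c(0, 0.6, 0.5), gamma = c(72, 40, 22))),
    class = "monowet_domain_error"
  )
})

test_that("threshold-angle profile starts at 66 degrees and never increases", {
  curve <- fit_mixture_tension(mixture_table_6pt)
  prof <- theta_ads_profile(curve, x_grid = seq(0, 0.2, by = 0.02))
  expect_equal(round(prof$theta_ads[1]), 66)
  expect_true(all(diff(prof$theta_ads) <= 1e-9))
  expect_false(any(prof$beyond_solubility[prof$x <= 0.2]))

  # compositions where the monolayer is favorable at every angle are marked
  full <- theta_ads_profile(curve, x_grid = c(0, 0.5, 1))
  expect_identical(full$status[full$x == 1], "always_adsorbs")
  expect_identical(full$theta_ads[full$x == 1], 0)
  expect_true(all(full$beyond_solubility[full$x > 0.2]))
})

test_that("profile solver agrees with an independent root oracle", {
  lin <- fit_mixture_tension(tibble::tibble(x = c(0, 1), gamma = c(72, 22)),
                             method = "linear")
  m <- adhesion_model()
  prof <- theta_ads_profile(lin, m, x_grid = 0.1)
  g <- predict(lin, 0.1)
  oracle <- uniroot(function(th) {
    m$wll / 2 - wsl_at(m, th) + g * cos(th * pi / 180)
  }, c(0, 180), tol = 1e-12)$root
  expect_lt(abs(prof$theta_ads - oracle), 1e-6)
})

test_that("free-energy profiles behave as the adhesion-tension model dictates", {
  curve <- fit_mixture_tension(mixture_table_6pt)
  m <- adhesion_model()

  # at the critical angle the profile is flat in composition
  theta_wc <- critical_water_angle(72, 22)
  flat <- free_energy_profile(curve, theta_wc, x_grid = seq(0, 0.2, 0.05))
  expect_lt(diff(range(flat$free_energy)), 1e-9)

  # all substrates converge to the neat-organic value at x = 1
  limit <- neat_organic_free_energy(m, gamma_alc = 22)
  conv <- free_energy_profile(curve, c(45, 66, 104, theta_wc),
                              x_grid = c(0, 1))
  at1 <- conv$free_energy[conv$x == 1]
  expect_true(all(abs(at1 - limit) < 1e-9))
  expect_true(all(conv$beyond_solubility[conv$x == 1]))

  # the oxidized-silicon-like substrate crosses zero near gamma = 35 mN/m
  # the crossing sits just past 20 mol%, where the model is flagged but
  # still evaluated
  prof45 <- free_energy_profile(curve, 45, x_grid = seq(0, 0.5, by = 0.001))
  i <- which(diff(sign(prof45$free_energy)) != 0)[1]
  frac <- prof45$free_energy[i] /
    (prof45$free_energy[i] - prof45$free_energy[i + 1])
  gamma_cross <- prof45$gamma[i] + frac * (prof45$gamma[i + 1] - prof45$gamma[i])
  expect_equal(gamma_cross, 35.129, tolerance = 0.01)

  # hydrophobic substrate above the critical angle: alcohol weakens adsorption
  prof104 <- free_energy_profile(curve, 104, x_grid = seq(0, 0.2, by = 0.05))
  expect_true(all(prof104$free_energy < 0))
  expect_true(all(diff(prof104$free_energy) > 0))
})

test_that("profile and curve objects expose tidy summaries and plots", {
  curve <- fit_mixture_tension(mixture_table_6pt)
  g <- glance(curve)
  expect_equal(g$gamma_w, 72)
  expect_equal(g$gamma_alc, 22)
  prof <- theta_ads_profile(curve, x_grid = seq(0, 0.2, 0.05))
  expect_s3_class(autoplot(prof), "ggplot")
  fe <- free_energy_profile(curve, c(45, 104), x_grid = seq(0, 0.2, 0.05))
  expect_s3_class(autoplot(fe), "ggplot")
})
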