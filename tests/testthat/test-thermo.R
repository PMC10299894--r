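test_that("wsl(theta) reproduces its anchor points and rejects bad angles", {
  m <- adhesion_model()
  expect_equal(wsl_at(m, 0), 57)
  expect_equal(wsl_at(m, 113), 52)
  m_const <- adhesion_model(wll = 49, wsl_intercept = 54, wsl_slope = 0)
  expect_equal(wsl_at(m_const, 90), 54)
  expect_error(wsl_at(m, -1), class = "monowet_domain_error")
  expect_error(wsl_at(m, 181), class = "monowet_domain_error")
  expect_error(adhesion_model(wll = -1), class = "monowet_domain_error")
  expect_error(adhesion_model(wsl_intercept = 10, wsl_slope = -1),
               class = "monowet_domain_error")
})

test_that("free-energy breakdown matches hand arithmetic and is additive", {
  br0 <- adsorption_free_energy(0)
  expect_equal(br0$total, 39.5)
  expect_equal(br0$term_ll, 24.5)
  expect_equal(br0$term_sl, -57)
  expect_equal(br0$term_adhesion, 72)

  br113 <- adsorption_free_energy(113)
  expect_equal(br113$total, 24.5 - 52 + 72 * cos(113 * pi / 180))
  expect_equal(br113$total, -55.6326, tolerance = 1e-4)

  # exact additivity across the full angle range
  grid <- adsorption_free_energy(seq(0, 180, by = 0.5))
  expect_true(all(abs(grid$total -
    (grid$term_ll + grid$term_sl + grid$term_adhesion)) < 1e-9))

  expect_error(adsorption_free_energy(90, gamma = 0),
               class = "monowet_domain_error")
  expect_error(adsorption_free_energy(190), class = "monowet_domain_error")
})

test_that("adsorption angle solver finds the water threshold near 66 degrees", {
  sol <- solve_adsorption_angle()
  expect_identical(sol$status, "root")
  expect_equal(sol$theta, 65.7328, tolerance = 1e-4)
  expect_identical(tidy(sol)$theta_int, 66)
  expect_lt(abs(sol$f_root), 1e-9)
  expect_identical(sol$n_roots, 1L)
  # the root satisfies the free energy being zero
  expect_lt(abs(adsorption_free_energy(sol$theta)$total), 1e-9)
})

test_that("solver root satisfies the implicit cosine fixed point", {
  for (gamma in c(72, 60, 40)) {
    sol <- solve_adsorption_angle(gamma = gamma)
    m <- adhesion_model()
    lhs <- cos(sol$theta * pi / 180)
    rhs <- (2 * wsl_at(m, sol$theta) - m$wll) / (2 * gamma)
    # compare as angles
    expect_lt(abs(acos(lhs) - acos(rhs)) * 180 / pi, 1e-6)
    # cross-check against an independent fixed-point iteration
    expect_lt(abs(sol$theta - fixed_point_theta_ads(m, gamma)), 1e-6)
  }
})

test_that("constant wsl at wll/2 puts the threshold at 90 degrees", {
  m <- adhesion_model(wll = 49, wsl_intercept = 24.5, wsl_slope = 0)
  for (gamma in c(72, 30, 10)) {
    expect_equal(solve_adsorption_angle(m, gamma)$theta, 90, tolerance = 1e-7)
  }
})

test_that("no-root cases are reported as typed outcomes, not failures", {
  # enormous bilayer-splitting cost: monolayer never favored
  never <- solve_adsorption_angle(adhesion_model(wll = 400), 72)
  expect_identical(never$status, "never_adsorbs")
  expect_true(is.na(never$theta))
  # strong substrate adhesion and weak solvent: always favored
  always <- solve_adsorption_angle(adhesion_model(), 22)
  expect_identical(always$status, "always_adsorbs")
  expect_true(is.na(always$theta))
})

test_that("free energy decreases monotonically over (5, 175) so the root is unique", {
  th <- seq(5, 175, by = 0.1)
  f <- adsorption_free_energy(th)$total
  expect_true(all(diff(f) < 0))
  expect_identical(sum(diff(sign(f)) != 0), 1L)
})

test_that("hydrocarbon approximation brackets the threshold at 67-71 degrees", {
  expect_equal(theta_ads_hydrocarbon(28, 72), 67.1146, tolerance = 1e-4)
  expect_equal(theta_ads_hydrocarbon(23, 72), 71.3707, tolerance = 1e-4)
  expect_equal(theta_ads_hydrocarbon(72, 72), 0)
  expect_error(theta_ads_hydrocarbon(80, 72), class = "monowet_domain_error")
  # a partially wetting hydrocarbon raises the threshold
  expect_gt(theta_ads_hydrocarbon(28, 72, theta_hc = 30),
            theta_ads_hydrocarbon(28, 72))
})

test_that("hydrocarbon closed form agrees with the implicit solver in its own limit", {
  for (gamma_hc in c(23, 25.5, 28)) {
    m <- adhesion_model(wll = 2 * gamma_hc, wsl_intercept = 2 * gamma_hc,
                        wsl_slope = 0)
    sol <- solve_adsorption_angle(m, 72)
    expect_lt(abs(sol$theta - theta_ads_hydrocarbon(gamma_hc, 72)), 1e-6)
  }
})

test_that("linearized free energy matches its closed form and error bound", {
  theta_ads <- solve_adsorption_angle()$theta
  expect_equal(linearized_free_energy(theta_ads, theta_ads), 0)
  expect_equal(linearized_free_energy(0, 65.7, 72), 42.3710, tolerance = 1e-4)
  expect_equal(linearized_free_energy(180, 90, 72), -72)

  # |linearized - exact| = |wsl(theta_ads) - wsl(theta)| <= |slope| * |theta - theta_ads|
  m <- adhesion_model()
  th <- seq(0, 180, by = 1)
  exact <- adsorption_free_energy(th)$total
  approx <- linearized_free_energy(th, theta_ads)
  expect_true(all(abs(approx - exact) <=
                    abs(m$wsl_slope) * abs(th - theta_ads) + 1e-9))
})

test_that("air-water free energy reduces to wll/2 - gamma", {
  expect_equal(air_water_free_energy(), -47.5)
  expect_equal(air_water_free_energy(adhesion_model(wll = 144), 72), 0)
  expect_equal(air_water_free_energy(gamma = 22), 2.5)
})

test_that("equivalent contact angle of the air-water interface is near 106 degrees", {
  eqv <- equivalent_contact_angle()
  expect_identical(eqv$status, "root")
  expect_equal(eqv$theta, 105.8663, tolerance = 1e-4)
  # at the root the substrate free energy equals the air-water one
  expect_equal(adsorption_free_energy(eqv$theta)$total,
               air_water_free_energy(), tolerance = 1e-9)
  # perfectly adhesive constant wsl = 2*gamma: cos(theta*) = 1
  m <- adhesion_model(wll = 49, wsl_intercept = 144, wsl_slope = 0)
  expect_equal(equivalent_contact_angle(m, 72)$theta, 0, tolerance = 1e-7)
  # wsl above 2*gamma everywhere: cos(theta*) would exceed 1, no root
  strong <- adhesion_model(wll = 49, wsl_intercept = 160, wsl_slope = 0)
  expect_identical(equivalent_contact_angle(strong, 72)$status,
                   "no_equivalent_angle")
})

test_that("neat-organic free energy defaults to wsl at the in-water threshold", {
  expect_equal(neat_organic_free_energy(), -7.5915, tolerance = 1e-4)
  expect_equal(neat_organic_free_energy(theta_eval = 0), -10.5)
  # wll = 2 * wsl cancels the adhesion terms, leaving gamma_alc
  m <- adhesion_model(wll = 49, wsl_intercept = 24.5, wsl_slope = 0)
  expect_equal(neat_organic_free_energy(m, gamma_alc = 22, theta_eval = 40), 22)
})

test_that("free_energy_curve pivots to long form and plots", {
  fc <- free_energy_curve(theta = seq(0, 180, by = 10))
  expect_s3_class(fc, "free_energy_curve")
  expect_setequal(unique(fc$component),
                  c("term_ll", "term_sl", "term_adhesion", "total"))
  expect_s3_class(autoplot(fc), "ggplot")
})
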