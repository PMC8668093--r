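test_that("expression clamp saturates at a3", {
  expect_equal(clamp_expression(0.5, 0.8), 0.5)
  expect_equal(clamp_expression(0.8, 0.8), 0.8)
  expect_equal(clamp_expression(2.0, 0.8), 0.8)
  expect_equal(clamp_expression(c(-1, 0.79, 5), 0.8), c(-1, 0.79, 0.8))
  expect_error(clamp_expression(1, a3 = 0), "a3")
})

test_that("hypocotyl converter matches closed-form integrals", {
  pars <- phenotype_params()
  at_level <- function(level)
    hypocotyl_length(make_trajectory("constant", mean = level, dt = 0.05), pars)
  # integrand identically zero at the baseline level
  expect_equal(at_level(pars$a2), 0, tolerance = 1e-12)
  # clamp active: 0.9 * 24 * (0.8 - 0.03103)
  expect_equal(at_level(1.0), 16.6098, tolerance = 1e-4)
  expect_equal(at_level(0.5), 0.9 * 24 * (0.5 - 0.03103), tolerance = 1e-9)
})

test_that("hypocotyl is monotone in ATHB2 and insensitive above the clamp", {
  tr_lo <- make_trajectory("sinusoid", mean = 0.3, amplitude = 0.1)
  tr_hi <- tr_lo
  tr_hi$species[, "ATHB2"] <- tr_hi$species[, "ATHB2"] + 0.05
  expect_gt(hypocotyl_length(tr_hi), hypocotyl_length(tr_lo))

  tr_a <- make_trajectory("constant", mean = 0.9)
  tr_b <- make_trajectory("constant", mean = 5)
  expect_equal(hypocotyl_length(tr_a), hypocotyl_length(tr_b))
})

test_that("FT area quadrature matches analytic areas", {
  expect_equal(ft_area(make_trajectory("constant", mean = 0)), 0)
  sin_tr <- make_trajectory("sinusoid", mean = 0.1, amplitude = 0.05, dt = 0.01)
  expect_equal(ft_area(sin_tr), 2.4, tolerance = 1e-6)
  tri <- make_trajectory("triangle", mean = 0.25, amplitude = 0.2, dt = 0.01)
  expect_equal(ft_area(tri), 0.25 * 24, tolerance = 1e-6)
})

test_that("flowering-time map: values, flags, pole, monotonicity", {
  pars <- phenotype_params()
  zero <- days_to_flower(0, pars)
  expect_equal(zero$days, 16.55 - 2308.141, tolerance = 1e-9)
  expect_setequal(zero$flags, c("NEGATIVE_DAYS", "FT_AREA_BELOW_A5"))

  big <- days_to_flower(1e6, pars)
  expect_equal(big$days, 16.55, tolerance = 0.05)
  expect_length(big$flags, 0)

  expect_error(days_to_flower(pars$a5, pars), "pole")
  expect_error(days_to_flower(-1, pars), ">= 0")

  # strictly decreasing above a5, bounded below by d0
  areas <- seq(0.05, 20, length.out = 60)
  days <- vapply(areas, function(a) days_to_flower(a, pars)$days, numeric(1))
  expect_true(all(diff(days) < 0))
  expect_true(all(days > pars$d0))
})

test_that("effective light duration converts days to duty-cycle light hours", {
  expect_equal(effective_light_duration(32.52, 12, 24), 390.24)
  expect_equal(effective_light_duration(24.79, 12, 18), 396.64, tolerance = 1e-10)
  expect_equal(effective_light_duration(0, 12, 24), 0)
  expect_error(effective_light_duration(10, 12, 0), "pr")
  # linear in days and in the duty cycle
  expect_equal(effective_light_duration(20, 6, 24),
               0.5 * effective_light_duration(20, 12, 24))
})

test_that("LED energy model reproduces driver-rating arithmetic", {
  expect_equal(round(energy_consumption(0.99, 18, 24), 2), 3.62)
  expect_equal(round(energy_consumption(1.00, 22, 24), 2), 4.47)
  expect_equal(round(energy_consumption(1.00, 28, 32), 2), 4.27)
  expect_equal(energy_consumption(0, 12, 24), 0)
  # linear in amplitude and duty cycle
  expect_equal(energy_consumption(0.5, 12, 24),
               0.5 * energy_consumption(1, 12, 24))
  expect_equal(energy_consumption(1, 6, 24),
               0.5 * energy_consumption(1, 12, 24))
  expect_error(energy_params(eta_led = 1.2), "eta_led")
  expect_error(energy_consumption(1, 12, 24, energy_params(n_days = 365)) < 0,
               NA)
})

test_that("phenotype bundle carries profile-derived schedule metrics", {
  tr <- make_toy_clock_trajectory(light_profile(), k = 5, dt = 0.05)
  res <- phenotypes(tr)
  expect_s3_class(res, "phenotype_result")
  expect_equal(res$ft_area, ft_area(tr))
  expect_equal(res$eldf_hours,
               effective_light_duration(res$days_to_flower, 12, 24))
  expect_equal(res$energy_mwh_per_year, energy_consumption(1, 12, 24))
  df <- as.data.frame(res)
  expect_named(df, c("days_to_flower", "hypocotyl_mm", "ft_area",
                     "eldf_hours", "energy_mwh_per_year", "flags"))
})

test_that("halving the output grid changes integrals by well under 0.1%", {
  prof <- light_profile()
  f1 <- sim_cached(prof, sim_settings(output_dt = 0.1))
  f2 <- sim_cached(prof, sim_settings(output_dt = 0.05))
  expect_lt(abs(f1$ft_area - f2$ft_area) / f2$ft_area, 0.001)
  expect_lt(abs(f1$hypocotyl_mm - f2$hypocotyl_mm) / f2$hypocotyl_mm, 0.001)
})
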