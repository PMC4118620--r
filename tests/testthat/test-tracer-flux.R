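test_that("exact lines are recovered with perfect linearity", {
  tc <- tibble::tibble(time_min = c(30, 60, 90, 120),
                       lactate_conc = 2 * c(30, 60, 90, 120))
  fit <- fit_lactate_flux(tc)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$linear_flag)
  g <- glance(fit)
  expect_equal(g$slope, 2)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], 2)
})

test_that("degenerate and insufficient time courses are handled", {
  flat <- tibble::tibble(time_min = c(30, 60, 90, 120),
                         lactate_conc = rep(5, 4))
  fit <- fit_lactate_flux(flat)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_false(fit$linear_flag)
  expect_error(fit_lactate_flux(tibble::tibble(time_min = c(30, 60),
                                               lactate_conc = c(1, 2))),
               "3 time points")
  expect_error(fit_lactate_flux(tibble::tibble(time_min = c(30, 30, 60),
                                               lactate_conc = 1:3)),
               "strictly increasing")
})

test_that("slope fitting is affine-equivariant and robust to point removal", {
  tc <- generate_tracer_timecourse(1.5, noise_sigma = 3, intercept = 10,
                                   seed = 8)
  s1 <- fit_lactate_flux(tc)$slope
  tc_scaled <- dplyr::mutate(tc, lactate_conc = lactate_conc * 7)
  expect_equal(fit_lactate_flux(tc_scaled)$slope, 7 * s1, tolerance = 1e-12)

  exact <- tibble::tibble(time_min = c(30, 60, 90, 120),
                          lactate_conc = 4 + 2 * c(30, 60, 90, 120))
  for (drop in 1:4) {
    expect_equal(fit_lactate_flux(exact[-drop, ])$slope, 2)
  }
})

test_that("noisy slope estimates are within statistical error of truth", {
  tc <- generate_tracer_timecourse(1.5, noise_sigma = 0.05 * 1.5 * 90,
                                   seed = 303)
  fit <- fit_lactate_flux(tc)
  expect_lt(abs(fit$slope - 1.5), 2 * fit$std_error + 1e-9)
})

test_that("occupancy model converts dose to fraction inhibited", {
  expect_equal(fraction_inhibited(1, 1), 0.5)
  expect_equal(fraction_inhibited(0, 1), 0)
  expect_equal(fraction_inhibited(3, 1), 0.75)
  doses <- seq(0, 50, by = 5)
  expect_true(all(diff(fraction_inhibited(doses, 7)) > 0))
  expect_true(all(fraction_inhibited(doses, 7) < 1))
  expect_error(fraction_inhibited(1, 0), "Ki")
  expect_error(fraction_inhibited(-1, 1), "non-negative")
})

test_that("empirical FCC recovers log-log slope identities", {
  f <- c(0, 0.1, 0.2, 0.3, 0.4)
  # flux unchanged: zero control
  p0 <- tibble::tibble(fraction_inhibited = f, flux = rep(2, 5))
  expect_equal(empirical_fcc(p0)$fcc, 0, tolerance = 1e-12)
  # flux proportional to residual activity: unit control
  p1 <- tibble::tibble(fraction_inhibited = f, flux = 3 * (1 - f))
  out <- empirical_fcc(p1)
  expect_equal(out$fcc, 1, tolerance = 1e-12)
  expect_true(out$window_respected)
  # all points beyond the small-perturbation window: warn, full-window fit
  p2 <- tibble::tibble(fraction_inhibited = c(0.6, 0.7, 0.8, 0.9),
                       flux = 3 * (1 - c(0.6, 0.7, 0.8, 0.9)))
  expect_warning(out2 <- empirical_fcc(p2), "window")
  expect_false(out2$window_respected)
  expect_equal(out2$fcc, 1, tolerance = 1e-12)
})

test_that("media glucose budget reproduces the imaging-experiment arithmetic", {
  b <- media_glucose_budget(100, 2000, 24, 400, 750)
  expect_equal(b$consumed_nmol_exact, 4.8)
  expect_equal(b$consumed_nmol, 5)
  expect_equal(b$available_nmol, 300)
  expect_true(b$excess_flag)
  expect_equal(media_glucose_budget(100, 0, 24, 400, 750)$consumed_nmol, 0)
})

test_that("grouped tracer tables are fitted per condition and replicate", {
  tab <- dplyr::bind_rows(
    generate_tracer_timecourse(1.2, condition = "veh", replicate = 1L),
    generate_tracer_timecourse(0.6, condition = "drug", replicate = 1L),
    generate_tracer_timecourse(0.6, condition = "drug", replicate = 2L)
  )
  fits <- fit_tracer_table(tab)
  expect_equal(nrow(fits), 3)
  expect_equal(fits$slope[fits$condition == "veh"], 1.2)
  expect_true(all(fits$linear_flag))
})
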