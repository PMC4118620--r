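test_that("the curated default set is Haldane-consistent by construction", {
  m <- default_model()
  for (nm in names(m$kinetics)) {
    p <- m$kinetics[[nm]]
    if (is.null(p$dG0)) next
    expect_equal(p$Vr, p$Vf * p$Kmr / (p$Kmf * keq_from_gibbs(p$dG0)),
                 tolerance = 1e-12)
  }
  # smoke: it supports a feasible steady state with physiological ATP
  sol <- default_steady()
  expect_true(sol$converged)
  expect_true(all(sol$state[SPECIES_INTRACELLULAR] > 0))
  expect_gte(sol$state[["ATP"]], 1)
  expect_lte(sol$state[["ATP"]], 5)
})

test_that("tracer generator round-trips and is seeded", {
  tc <- generate_tracer_timecourse(1.5)
  expect_equal(tc$time_min, c(30, 60, 90, 120))
  expect_equal(fit_lactate_flux(tc)$slope, 1.5)
  expect_equal(fit_lactate_flux(tc)$r_squared, 1)
  t1 <- generate_tracer_timecourse(1.5, noise_sigma = 4, seed = 10)
  t2 <- generate_tracer_timecourse(1.5, noise_sigma = 4, seed = 10)
  expect_identical(t1, t2)
})

test_that("least-squares slopes are unbiased over seeded replicates", {
  true_flux <- 1.5
  sigma <- 0.05 * true_flux * 90  # 5% of the response range
  slopes <- vapply(1:200, function(s) {
    fit_lactate_flux(generate_tracer_timecourse(true_flux,
                                                noise_sigma = sigma,
                                                seed = 1000 + s))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - true_flux) / true_flux, 0.01)
})

test_that("the default perturbation panel has the designed 42 experiments", {
  cfg <- panel_config(noise_sigma = 0, seed = 2)
  conditions <- glycomca:::panel_conditions(cfg)
  expect_equal(nrow(conditions), 14)
  panel <- generate_perturbation_panel(default_model(), cfg)
  expect_equal(nrow(panel), 42)
  expect_equal(length(unique(panel$condition)), 14)
  expect_equal(unname(table(panel$condition)), rep(3L, 14),
               ignore_attr = TRUE)

  # vehicles at zero dose and zero noise are exactly the baseline state
  base <- default_steady()
  veh <- panel[panel$compound == "vehicle" & panel$replicate == 1, ]
  expect_equal(veh$J_Lac[1], unname(base$fluxes[["LDH"]]), tolerance = 1e-8)
  expect_equal(veh$conc_FBP[1], unname(base$state[["FBP"]]),
               tolerance = 1e-8)

  # GAPDH inhibition signature: hexose phosphates accumulate upstream,
  # lower-glycolysis intermediates are depleted (highest dose with a
  # converged steady state; conditions that orbit an oscillation are
  # recorded as missing by contract)
  ia_top <- panel[panel$compound == "IA" & panel$replicate == 1 &
                    panel$converged, ]
  ia_top <- ia_top[which.max(ia_top$dose_uM), ]
  hp_up <- (ia_top$conc_FBP + ia_top$conc_G6P + ia_top$conc_F6P) /
    (veh$conc_FBP[1] + veh$conc_G6P[1] + veh$conc_F6P[1])
  down_dn <- (ia_top$conc_PG3 + ia_top$conc_PEP + ia_top$conc_PYR) /
    (veh$conc_PG3[1] + veh$conc_PEP[1] + veh$conc_PYR[1])
  expect_gt(hp_up, 1)
  expect_lt(down_dn, 1)
})

test_that("panel noise is reproducible from the seed", {
  cfg <- panel_config(noise_sigma = 0.1, seed = 9)
  p1 <- generate_perturbation_panel(default_model(), cfg)
  p2 <- generate_perturbation_panel(default_model(), cfg)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("dose-response simulation is deterministic and edge-safe", {
  m <- default_model()
  expect_equal(nrow(simulate_dose_response(m, "LDH", numeric(), 8)), 0)
  dr <- simulate_dose_response(m, "LDH", c(4, 4), 8)
  expect_equal(dr$flux[1], dr$flux[2])
  expect_equal(dr$fraction_inhibited, c(1 / 3, 1 / 3))
})

test_that("in-silico dose panels agree with the analytic control coefficient", {
  m <- default_model()
  st <- default_steady()$state
  for (target in c("GAPDH", "LDH")) {
    fcc_model <- compute_fcc(m, target, st)
    Ki <- 10
    # small doses: residual activity 0.98 down to 0.80
    doses <- Ki * (1 / c(0.98, 0.93, 0.88, 0.84, 0.80) - 1)
    dr <- simulate_dose_response(m, target, doses, Ki)
    dr <- dr[dr$converged, ]
    est <- empirical_fcc(dr)$fcc
    expect_lt(abs(est - fcc_model), pmax(0.15 * abs(fcc_model), 0.02))
  }
})
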