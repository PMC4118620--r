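RT <- 8.314e-3 * 310.15

test_that("equilibrium constant follows the Gibbs relation", {
  expect_equal(keq_from_gibbs(0), 1)
  expect_equal(keq_from_gibbs(-RT * log(10)), 10)
  expect_equal(keq_from_gibbs(RT * log(4)), 0.25)
  # monotone decreasing in dG0
  dg <- seq(-40, 40, length.out = 25)
  expect_true(all(diff(keq_from_gibbs(dg)) < 0))
  expect_error(keq_from_gibbs(NaN), "finite")
  expect_error(keq_from_gibbs(5, temperature = -1), "positive")
})

test_that("Haldane relation ties reverse to forward capacity", {
  expect_equal(haldane_reverse_vmax(1, 1, 1, 1), 1)
  expect_equal(haldane_reverse_vmax(2, 0.5, 1, 4), 1)
  # irreversible limit
  expect_lt(haldane_reverse_vmax(1, 1, 1, 1e12), 1e-11)
  expect_error(haldane_reverse_vmax(1, 1, 1, 0), "Keq")
  expect_error(haldane_reverse_vmax(1, -1, 1, 1), "Keq")
})

test_that("control function multiplies saturable regulator terms", {
  expect_equal(control_function(1, 1, "activator"), 0.5)
  expect_equal(control_function(0, 1, "inhibitor"), 1)
  expect_equal(control_function(c(1, 1), c(1, 1),
                                c("activator", "inhibitor")), 0.25)
  expect_equal(control_function(numeric(), numeric(), character()), 1)
  expect_error(control_function(-1, 1, "activator"), ">= 0")
})

test_that("one-step rate law honors equilibrium, saturation and half-max", {
  # at S = P * Vr/Vf the numerator vanishes
  expect_equal(rate_one_step(0.5 * 2, 2, Vfmax = 3, Vrmax = 1.5), 0)
  # saturation limit: S >> 1, P = 0 approaches Vfmax * chi
  expect_equal(rate_one_step(1e9, 0, 4, 1, chi = 0.7), 4 * 0.7,
               tolerance = 1e-6)
  # substrates at their lumped Km, no product: half-max
  expect_equal(rate_one_step(1, 0, 4, 1), 2)
})

test_that("random bi-bi law is zero at Haldane equilibrium and signed", {
  Vf <- 5; Kmf <- 0.1; Kmr <- 2; Keq <- 8
  Vr <- haldane_reverse_vmax(Vf, Kmf, Kmr, Keq)
  # concentrations with mass-action ratio exactly Keq
  S1 <- 0.4; S2 <- 0.3; P2 <- 0.5
  P1 <- Keq * S1 * S2 / P2
  r <- rate_random_bibi(S1, S2, P1, P2, Vf, Vr, Kmf, Kmr, 0.2, 0.3, 1, 0.5)
  expect_equal(r, 0, tolerance = 1e-12)
  # no substrate: strictly reverse
  expect_lt(rate_random_bibi(0, 0, 1, 1, Vf, Vr, Kmf, Kmr,
                             0.2, 0.3, 1, 0.5), 0)
  # dominant forward binary term approaches Vfmax
  expect_equal(rate_random_bibi(1e4, 1e4, 0, 0, Vf, Vr, Kmf, Kmr,
                                1e6, 1e6, 1, 0.5), Vf, tolerance = 1e-3)
})

test_that("ordered bi-bi is cofactor-gated and dominates random in magnitude", {
  Vf <- 5; Kmf <- 0.1; Kmr <- 2; Keq <- 8
  Vr <- haldane_reverse_vmax(Vf, Kmf, Kmr, Keq)
  S1 <- 0.4; S2 <- 0.3; P2 <- 0.5
  P1 <- Keq * S1 * S2 / P2
  expect_equal(rate_ordered_bibi(S1, S2, P1, P2, Vf, Vr, Kmf, Kmr,
                                 0.2, 0.3, 1, 0.5), 0, tolerance = 1e-12)
  # both cofactors absent: numerator vanishes regardless of S1/P1
  expect_equal(rate_ordered_bibi(7, 0, 3, 0, Vf, Vr, Kmf, Kmr,
                                 0.2, 0.3, 1, 0.5), 0)
  # brute-force grid: ordered denominator lacks two terms, so |ordered| >=
  # |random| for identical parameters
  grid <- expand.grid(S1 = c(0, 0.1, 1), S2 = c(0, 0.2, 2),
                      P1 = c(0, 0.5, 3), P2 = c(0, 0.1, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ro <- rate_ordered_bibi(g$S1, g$S2, g$P1, g$P2, Vf, Vr, Kmf, Kmr,
                            0.2, 0.3, 1, 0.5)
    rr <- rate_random_bibi(g$S1, g$S2, g$P1, g$P2, Vf, Vr, Kmf, Kmr,
                           0.2, 0.3, 1, 0.5)
    expect_gte(abs(ro) - abs(rr), -1e-12)
  }
})

test_that("ter-bi law handles equilibrium, missing substrate, saturation", {
  Vf <- 10; Kmf <- 0.01; Kmr <- 1e-3; Keq <- 5e-4
  Vr <- haldane_reverse_vmax(Vf, Kmf, Kmr, Keq)
  S <- c(0.05, 0.5, 2); P2 <- 0.003
  P1 <- Keq * prod(S) / P2
  r <- rate_ter_bi(S[1], S[2], S[3], P1, P2, Vf, Vr, Kmf, Kmr,
                   0.1, 0.06, 1.5, 0.01, 0.01)
  expect_equal(r, 0, tolerance = 1e-12)
  # no phosphate: forward term zero, net non-positive
  expect_lte(rate_ter_bi(1, 1, 0, 0.01, 0.01, Vf, Vr, Kmf, Kmr,
                         0.1, 0.06, 1.5, 0.01, 0.01), 0)
  # saturating ternary term, no products
  expect_equal(rate_ter_bi(100, 100, 100, 0, 0, Vf, Vr, 1, Kmr,
                           1e9, 1e9, 1e9, 0.01, 0.01), Vf, tolerance = 1e-3)
})

test_that("transport laws: gradient-driven, antisymmetric, saturable", {
  expect_equal(transport_facilitated(2, 2, 5, 1.5), 0)
  expect_equal(transport_facilitated(1.5, 0, 5, 1.5), 2.5)
  expect_equal(transport_facilitated(1e9, 1, 5, 1.5), 5, tolerance = 1e-6)
  expect_equal(transport_facilitated(3, 1, 5, 1.5),
               -transport_facilitated(1, 3, 5, 1.5))
  expect_equal(transport_passive(0.1, 0.05, 2), 0.1)
  expect_equal(transport_passive(1, 1, 7), 0)
  expect_equal(transport_passive(0.1, 0.05, 4),
               2 * transport_passive(0.1, 0.05, 2))
})

test_that("shuttle balance is the oxidation plus serine-branch total", {
  expect_equal(shuttle_flux(1, 0.5), 2)
  expect_equal(shuttle_flux(0, 0), 0)
  expect_equal(shuttle_flux(3, 0), 3)
})

test_that("rate laws are bounded and thermodynamically signed at random states", {
  set.seed(99)
  Vf <- 5; Kmf <- 0.1; Kmr <- 2; Keq <- 8
  Vr <- haldane_reverse_vmax(Vf, Kmf, Kmr, Keq)
  for (i in 1:50) {
    x <- exp(runif(4, -4, 2))
    r <- rate_random_bibi(x[1], x[2], x[3], x[4], Vf, Vr, Kmf, Kmr,
                          0.2, 0.3, 1, 0.5)
    gamma <- (x[3] * x[4]) / (x[1] * x[2])
    expect_lte(abs(r), max(Vf, Vr))
    expect_identical(sign(r), sign(1 - gamma / Keq))
  }
})
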