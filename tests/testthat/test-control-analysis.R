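test_that("a pure rate-limiting step carries all flux control in a toy chain", {
  # independent two-step chain oracle, built from the rate-law primitives
  # with a brute-force steady state: S0 --E1 (irreversible, saturated)--> X
  # --E2 (fast, first order)--> P. The pathway flux is E1's capacity, so
  # FCC(E1) -> 1 and FCC(E2) -> 0.
  chain_flux <- function(V1, k2) {
    # X rises until k2 * X = V1 * S/(K+S) with S fixed and saturating
    S <- 1e5; K <- 1
    J1 <- function(x) V1 * S / (K + S)
    x_ss <- stats::uniroot(function(x) J1(x) - k2 * x,
                           c(1e-12, 1e12), tol = 1e-12)$root
    k2 * x_ss
  }
  d <- 0.01
  fcc1 <- (log(chain_flux(2 * exp(d), 5)) - log(chain_flux(2 * exp(-d), 5))) /
    (2 * d)
  fcc2 <- (log(chain_flux(2, 5 * exp(d))) - log(chain_flux(2, 5 * exp(-d)))) /
    (2 * d)
  expect_equal(fcc1, 1, tolerance = 1e-4)
  expect_equal(fcc2, 0, tolerance = 1e-4)
})

test_that("scaling every capacity scales lactate flux proportionally", {
  # the homogeneity behind the summation theorem, verified on the model
  m <- default_model()
  sol <- default_steady()
  lam <- 1.25
  params2 <- scale_activity(m$params, stats::setNames(
    rep(lam, length(CONTROLLABLE_STEPS)), CONTROLLABLE_STEPS))
  m2 <- glycolysis_model(params2)
  sol2 <- solve_steady_state(m2, init = sol$state, warm_start = TRUE)
  expect_true(sol2$converged)
  expect_lt(max(abs(sol2$state - sol$state) / pmax(sol$state, 1e-9)), 1e-6)
  expect_equal(sol2$fluxes[["LDH"]], lam * sol$fluxes[["LDH"]],
               tolerance = 1e-6)
})

test_that("FCC summation is within 0.05 of 1 on the default realization", {
  m <- default_model()
  fcc <- fcc_vector(m, default_steady()$state)
  expect_true(all(is.finite(fcc)))
  expect_lt(abs(fcc_summation(fcc) - 1), 0.05)
})

test_that("fcc_summation handles degenerate vectors", {
  expect_equal(fcc_summation(c(A = 1, B = 0, C = 0)), 1)
  expect_warning(s <- fcc_summation(numeric()), "empty")
  expect_equal(s, 0)
})

test_that("FCC estimates are stable in delta and differencing scheme", {
  m <- default_model()
  st <- default_steady()$state
  f1 <- fcc_vector(m, st, delta = 0.01)
  f2 <- fcc_vector(m, st, delta = 0.02)
  # linear-response regime: moderate coefficients are insensitive to delta
  mod <- abs(f1) <= 1
  expect_lt(max(abs(f1[mod] - f2[mod])), 1e-3)
  # large coefficients still agree to a relative 1%
  expect_lt(max(abs(f1 - f2) / pmax(abs(f1), 1)), 0.01)
  ffwd <- fcc_vector(m, st, delta = 0.01, method = "forward")
  expect_lt(max(abs(f1 - ffwd)), 1e-2)
})

test_that("correlation maps match a brute-force rank oracle and cluster sanely", {
  df <- toy_ensemble(tibble::tibble(
    a = c(1, 2, 3, 4, 5),
    b = c(2, 4, 6, 8, 10),       # perfectly correlated with a
    c = c(5, 4, 3, 2, 1),        # anti-correlated
    d = c(2.5, 1.0, 4.0, 3.0, 5.5)
  ))
  cm <- cluster_control_map(df, rows = c("a", "b", "c", "d"),
                            cols = c("a", "b", "c", "d"),
                            method = "spearman")
  expect_equal(cm$matrix["a", "b"], 1)
  expect_equal(cm$matrix["a", "c"], -1)
  expect_equal(unname(diag(cm$matrix)), rep(1, 4))
  expect_true(all(abs(cm$matrix) <= 1))
  # brute-force Spearman via ranks for every pair
  for (i in c("a", "b", "c", "d")) {
    for (j in c("a", "b", "c", "d")) {
      expect_equal(cm$matrix[i, j],
                   stats::cor(rank(df[[i]]), rank(df[[j]])),
                   tolerance = 1e-12)
    }
  }
  # perfectly correlated variables cluster adjacently
  ord <- cm$row_order
  expect_equal(abs(which(ord == "a") - which(ord == "b")), 1)
  # tidy view is long and complete
  td <- tidy(cm)
  expect_equal(nrow(td), 16)
})

test_that("constant columns yield missing correlations, not errors", {
  df <- toy_ensemble(tibble::tibble(a = 1:5, k = rep(2, 5)))
  cm <- cluster_control_map(df, rows = "a", cols = c("a", "k"))
  expect_true(is.na(cm$matrix["a", "k"]))
  expect_error(cluster_control_map(toy_ensemble(tibble::tibble(a = 1:2)),
                                   "a", "a"), "at least 3")
})
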