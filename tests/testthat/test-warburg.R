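test_that("Warburg ratio and lactate fraction follow the definition", {
  w <- warburg_effect(19, 1)
  expect_equal(w$W, 19)
  expect_equal(w$lactate_fraction, 0.95)
  expect_equal(warburg_effect(0, 2)$W, 0)
  expect_equal(warburg_effect(0, 2)$lactate_fraction, 0)
  # W = 1 is the oxidative/fermentative boundary
  expect_equal(warburg_effect(3, 3)$lactate_fraction, 0.5)
  expect_error(warburg_effect(1, 0), "rejected")
})

test_that("lactate fraction is a monotone rank-preserving transform of W", {
  set.seed(12)
  W <- exp(rnorm(100, 0, 2))
  frac <- W / (1 + W)
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(rank(W), rank(frac))
})

test_that("WE correlations recover exact linear relations", {
  df <- toy_ensemble(tibble::tibble(
    W = c(0.2, 1, 3, 8, 20),
    conc_GLC = c(0.2, 1, 3, 8, 20),          # identical to W
    conc_G6P = 100 - c(0.2, 1, 3, 8, 20),    # exactly -W plus offset
    conc_F6P = rep(1, 5)                     # constant -> missing
  ))
  for (v in setdiff(we_cols <- c("conc_FBP", "conc_DHAP", "conc_GAP",
                                 "conc_BPG", "conc_PG3", "conc_PG2",
                                 "conc_PEP", "conc_PYR", "conc_LAC"), "")) {
    df[[v]] <- runif(5)
  }
  out <- correlate_we(df, "metabolites")
  expect_equal(out$correlation[out$variable == "conc_GLC"], 1)
  expect_equal(out$correlation[out$variable == "conc_G6P"], -1)
  expect_true(is.na(out$correlation[out$variable == "conc_F6P"]))
  expect_error(correlate_we(df[1:2, ], "metabolites"), "at least 3")
})

test_that("FBP split separates micromolar from millimolar states", {
  labs <- fbp_state_split(c(0.1, 0.2, 5, 8))
  expect_equal(as.character(labs), c("low", "low", "high", "high"))
  expect_true(all(fbp_state_split(rep(0.3, 4)) == "low"))
  # two-component recovery on a well-separated log-normal mixture
  set.seed(77)
  truth <- rep(c("low", "high"), each = 300)
  x <- c(exp(rnorm(300, log(0.3), 0.35)), exp(rnorm(300, log(5), 0.35)))
  labs2 <- fbp_state_split(x, method = "two_component_split")
  expect_gte(mean(as.character(labs2) == truth), 0.99)
  # the 1-D split is contiguous: every low value below every high value
  expect_lt(max(x[labs2 == "low"]), min(x[labs2 == "high"]))
  expect_warning(fbp_state_split(rep(2, 5), method = "two_component_split"),
                 "identical")
})

test_that("state-conditioned correlations match a rank oracle and ignore order", {
  df <- tibble::tibble(
    J_Lac = c(1, 2, 3, 4, 5, 6),
    conc_GLC = c(2, 3, 5, 7, 8, 11),   # monotone with J_Lac
    conc_FBP = c(0.1, 0.2, 0.3, 5, 6, 7)
  )
  for (v in c("conc_G6P", "conc_F6P", "conc_DHAP", "conc_GAP", "conc_BPG",
              "conc_PG3", "conc_PG2", "conc_PEP", "conc_PYR", "conc_LAC")) {
    df[[v]] <- c(3, 1, 4, 1, 5, 9) + seq_len(6) / 10
  }
  ens <- toy_ensemble(df)
  labels <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  out <- state_conditioned_correlations(ens, labels)
  glc_low <- out$correlation[out$state == "low" & out$variable == "conc_GLC"]
  expect_equal(glc_low, 1)
  # brute-force oracle within the high state
  oracle <- stats::cor(rank(df$J_Lac[4:6]), rank(df$conc_G6P[4:6]))
  expect_equal(out$correlation[out$state == "high" &
                                 out$variable == "conc_G6P"], oracle)
  # permutation invariance
  perm <- sample(6)
  out2 <- state_conditioned_correlations(toy_ensemble(df[perm, ]),
                                         labels[perm])
  expect_equal(dplyr::arrange(out2, .data$state, .data$variable),
               dplyr::arrange(out, .data$state, .data$variable))
})

test_that("density summary is a proper normalized estimate with a mode", {
  d <- density_summary(rep(3.2, 10))
  expect_equal(d$mode, 3.2)
  expect_false(d$bimodal)

  set.seed(5)
  u <- runif(5000)
  du <- density_summary(u, n_bins = 10)
  widths <- diff(range(u)) / 10
  expect_equal(sum(du$density$density * widths), 1, tolerance = 1e-9)
  expect_lt(max(abs(du$density$density - 1)), 0.25)
  expect_false(du$bimodal)

  # clearly bimodal mixture is flagged and its mode sits in a component
  x <- c(rnorm(400, 1, 0.15), rnorm(400, 4, 0.3))
  db <- density_summary(x, n_bins = 30)
  expect_true(db$bimodal)
  expect_lt(abs(db$mode - 1), 0.5)
})
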