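# Latin hypercube ensemble over enzyme-activity space.

#' Latin hypercube sample of enzyme activities
#'
#' Stratified sampling of multiplicative activity factors: for each sampled
#' parameter the range `[baseline/range_factor, baseline*range_factor]`
#' (log-spaced by default) is divided into `n` equal subintervals, one draw is
#' placed uniformly inside each subinterval, and the `n` values are randomly
#' permuted independently per parameter. Deterministic given the seed.
#'
#' @param n Number of draws.
#' @param baseline Named numeric vector of baseline activities (> 0).
#' @param range_factor Fold-range on either side of baseline (default 10, the
#'   two-orders-of-magnitude design).
#' @param log_scale Stratify on the log axis (default `TRUE`); set `FALSE`
#'   for linear stratification over the same interval.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble with `n` rows, one column per parameter, values are
#'   absolute activities (not factors).
#' @export
lhs_sample <- function(n, baseline, range_factor = 10, log_scale = TRUE,
                       seed = NULL) {
  stopifnot(all(baseline > 0), range_factor > 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(baseline)), names(baseline))))
  }
  cols <- lapply(names(baseline), function(nm) {
    lo <- baseline[[nm]] / range_factor
    hi <- baseline[[nm]] * range_factor
    if (log_scale) {
      edges <- exp(seq(log(lo), log(hi), length.out = n + 1))
      draws <- exp(log(edges[1:n]) +
                     stats::runif(n) * diff(log(edges))[1])
    } else {
      edges <- seq(lo, hi, length.out = n + 1)
      draws <- edges[1:n] + stats::runif(n) * diff(edges)[1]
    }
    sample(draws)
  })
  tibble::as_tibble(stats::setNames(cols, names(baseline)))
}

REJECTION_REASONS <- c("none", "no_convergence", "negative_state",
                       "nonpositive_glycolytic_flux",
                       "thermodynamic_violation", "instability")

#' Feasibility filter for one solved realization
#'
#' A realization is accepted only if (a) the steady-state solve converged,
#' (b) every steady concentration is positive and below the physical cap,
#' (c) net glucose uptake is strictly positive (a positive net flux through
#' glycolysis is required), (d) no reversible reaction's net flux contradicts
#' its thermodynamic driving force, and (e) the steady state is locally
#' stable (no Jacobian eigenvalue with real part above tolerance).
#'
#' @param model The (realization-specific) `glyco_model`.
#' @param sol Result of [solve_steady_state()].
#' @param conc_cap Physical concentration cap in mM (default 100).
#' @param eig_tol Eigenvalue real-part tolerance (default 1e-6).
#' @return List with `accepted` (logical) and `reason` (one of `"none"`,
#'   `"no_convergence"`, `"negative_state"`, `"nonpositive_glycolytic_flux"`,
#'   `"thermodynamic_violation"`, `"instability"`).
#' @export
feasibility_filter <- function(model, sol, conc_cap = 100, eig_tol = 1e-6) {
  reject <- function(reason) list(accepted = FALSE, reason = reason)
  if (!isTRUE(sol$converged)) return(reject("no_convergence"))
  dyn <- sol$state[SPECIES_INTRACELLULAR]
  if (any(dyn <= 0) || any(dyn > conc_cap)) return(reject("negative_state"))
  if (sol$fluxes[["GTR"]] <= 0) return(reject("nonpositive_glycolytic_flux"))
  audit <- thermodynamic_audit(model, sol$state)
  if (!all(audit$consistent)) return(reject("thermodynamic_violation"))
  if (is.null(sol$jacobian)) return(reject("no_convergence"))
  ev <- eigen(sol$jacobian, only.values = TRUE)$values
  if (max(Re(ev)) > eig_tol) return(reject("instability"))
  list(accepted = TRUE, reason = "none")
}

# Derived per-realization quantities used across the statistics modules.
derived_quantities <- function(state, fluxes) {
  J_Lac <- fluxes[["LDH"]]
  J_Ox <- fluxes[["OXPHOS"]]
  W <- if (J_Ox > 0) J_Lac / J_Ox else NA_real_
  tibble::tibble(
    J_Lac = J_Lac, J_Ox = J_Ox, W = W,
    lactate_fraction = if (!is.na(W) && W >= 0) W / (1 + W) else NA_real_,
    ATP_ADP = state[["ATP"]] / state[["ADP"]],
    NADH_NAD = state[["NADH"]] / state[["NAD"]],
    glucose_uptake = fluxes[["GTR"]]
  )
}

#' Run a Monte Carlo ensemble over enzyme-activity space
#'
#' Draws a Latin hypercube over the sampled activities, solves every
#' realization to steady state, applies [feasibility_filter()], and collects
#' one row per draw: the sampled activities (`vmax_*` columns), steady-state
#' concentrations (`conc_*`), net fluxes (`flux_*`), derived Warburg/energy/
#' redox quantities, and the acceptance flag with its rejection reason.
#' Individual solver failures are recorded as rejections, never raised.
#'
#' @param model Baseline `glyco_model` (defines the centre of the ranges).
#' @param n Number of draws (the study design uses 2000-5000; scale down for
#'   quick exploration).
#' @param seed Integer seed for reproducibility.
#' @param sampled Character vector of steps whose activities are randomized
#'   (default: every enzyme and transporter capacity plus OxPhos and ATPase;
#'   Michaelis constants are never randomized).
#' @param range_factor,log_scale Passed to [lhs_sample()].
#' @param conc_cap,eig_tol Passed to [feasibility_filter()].
#' @return A tibble of class `glyco_ensemble` with attributes `seed`,
#'   `acceptance_rate` and `config`.
#' @export
run_ensemble <- function(model, n, seed = 1L,
                         sampled = default_sampled_steps(),
                         range_factor = 10, log_scale = TRUE,
                         conc_cap = 100, eig_tol = 1e-6) {
  baseline <- step_activities(model$params, sampled)
  draws <- lhs_sample(n, baseline, range_factor, log_scale, seed)
  base_init <- initial_state(model$params)

  rows <- purrr::map_dfr(seq_len(nrow(draws)), function(i) {
    factors <- unlist(draws[i, ]) / baseline
    params_i <- scale_activity(model$params, factors)
    model_i <- glycolysis_model(params_i)
    sol <- solve_steady_state(model_i, init = base_init)
    verdict <- feasibility_filter(model_i, sol, conc_cap, eig_tol)
    out <- tibble::tibble(
      draw = i, accepted = verdict$accepted, rejection_reason = verdict$reason
    )
    vm <- tibble::as_tibble(as.list(stats::setNames(
      unlist(draws[i, ]), paste0("vmax_", names(baseline)))))
    conc <- tibble::as_tibble(as.list(stats::setNames(
      sol$state[SPECIES_INTRACELLULAR],
      paste0("conc_", SPECIES_INTRACELLULAR))))
    flux <- tibble::as_tibble(as.list(stats::setNames(
      sol$fluxes, paste0("flux_", names(sol$fluxes)))))
    dplyr::bind_cols(out, vm, conc, flux, derived_quantities(sol$state,
                                                            sol$fluxes))
  })

  structure(
    rows,
    class = c("glyco_ensemble", class(rows)),
    seed = seed,
    acceptance_rate = mean(rows$accepted),
    config = list(n = n, sampled = sampled, range_factor = range_factor,
                  log_scale = log_scale, conc_cap = conc_cap,
                  eig_tol = eig_tol)
  )
}

#' Default randomized steps for the ensemble
#'
#' The enzyme-expression capacities varied in the Monte Carlo design: the ten
#' glycolytic enzymes plus glucose and lactate transport, the F26BP cycle,
#' the serine branch, mitochondrial oxidation and ATP demand.
#'
#' @return Character vector of step identifiers.
#' @export
default_sampled_steps <- function() {
  c("GTR", "HK", "PGI", "PFK", "PFK2", "ALD", "TPI", "GAPDH", "PGK",
    "PGM", "ENO", "PK", "LDH", "PHGDH", "MCT", "OXPHOS", "ATPASE")
}

#' Accepted subset of an ensemble table
#'
#' @param ensemble A `glyco_ensemble` tibble.
#' @return Tibble of accepted rows.
#' @export
accepted_realizations <- function(ensemble) {
  dplyr::filter(ensemble, .data$accepted)
}

#' Acceptance-rate summary of an ensemble
#'
#' @param ensemble A `glyco_ensemble` tibble.
#' @return One-row tibble: draws, accepted count, acceptance rate, and one
#'   count column per rejection reason.
#' @export
ensemble_summary <- function(ensemble) {
  counts <- table(factor(ensemble$rejection_reason,
                         levels = REJECTION_REASONS))
  dplyr::bind_cols(
    tibble::tibble(
      n = nrow(ensemble),
      n_accepted = sum(ensemble$accepted),
      acceptance_rate = mean(ensemble$accepted)
    ),
    tibble::as_tibble(as.list(counts))
  )
}
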