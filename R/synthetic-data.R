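# Seeded generators standing in for the study's raw data: inhibitor
# perturbation panels, tracer time courses, and model-driven dose-response
# panels. Everything is reproducible from (config, seed); no file or network
# access anywhere.

#' Default inhibitor panel configuration
#'
#' Three compounds targeting glycolysis at different points (3PO -> PFK2,
#' iodoacetate -> GAPDH, FX11 -> LDH), four log-spaced doses each spanning
#' residual activity roughly 0.9 to 0.2, plus two vehicle conditions, all in
#' triplicate: 3 x 4 + 2 = 14 conditions, 42 experiments.
#'
#' @param noise_sigma Multiplicative log-normal noise sd on metabolite levels
#'   and fluxes (default 0.1, an LC-MS-like relative error).
#' @param replicates Replicates per condition (default 3).
#' @param seed Integer seed.
#' @return List of class `glyco_panel_config`.
#' @export
panel_config <- function(noise_sigma = 0.1, replicates = 3, seed = 1L) {
  compounds <- tibble::tibble(
    compound = c("3PO", "IA", "FX11"),
    target = c("PFK2", "GAPDH", "LDH"),
    Ki_uM = c(25, 10, 8)
  )
  # residual activity 1/(1+dose/Ki): doses at Ki*c give residuals
  # {0.9, 0.65, 0.4, 0.2}
  dose_over_ki <- c(1 / 9, 0.55, 1.5, 4)
  doses <- tidyr::crossing(compounds, level = seq_along(dose_over_ki)) |>
    dplyr::mutate(dose_uM = .data$Ki_uM * dose_over_ki[.data$level])
  structure(
    list(compounds = compounds, doses = doses,
         vehicles = c("vehicle_1", "vehicle_2"),
         replicates = replicates, noise_sigma = noise_sigma, seed = seed),
    class = "glyco_panel_config"
  )
}

panel_conditions <- function(config) {
  drug <- config$doses |>
    dplyr::mutate(condition = paste0(.data$compound, "_", .data$level))
  veh <- tibble::tibble(
    compound = "vehicle", target = NA_character_, Ki_uM = NA_real_,
    level = 0L, dose_uM = 0, condition = config$vehicles
  )
  dplyr::bind_rows(
    veh, drug[c("compound", "target", "Ki_uM", "level", "dose_uM",
                "condition")]
  )
}

#' Generate a simulated inhibitor perturbation panel
#'
#' For each condition, scales the target enzyme's capacity by
#' `1 - fraction_inhibited(dose, Ki)`, re-solves the steady state, and
#' records metabolite levels and the lactate flux with seeded multiplicative
#' log-normal noise per replicate. Vehicles are the unperturbed model.
#' Non-converging conditions are recorded with `NA` measurements; the panel
#' is always returned.
#'
#' @param model Baseline `glyco_model`.
#' @param config A `glyco_panel_config` (default [panel_config()]).
#' @return Tibble with one row per experiment (condition x replicate):
#'   compound, target, dose, fraction inhibited, `conc_*` metabolite levels
#'   (mM) and `J_Lac` (mM/hr).
#' @export
generate_perturbation_panel <- function(model, config = panel_config()) {
  conditions <- panel_conditions(config)
  base_init <- initial_state(model$params)
  set.seed(config$seed)

  # solve dose series per compound by continuation: each dose warm-starts
  # from the previous dose's root, which tracks the physically connected
  # branch and is far more robust than restarting from baseline
  warm <- list()
  solved <- purrr::map(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    if (row$compound == "vehicle") {
      model_i <- model
      fi <- 0
    } else {
      fi <- fraction_inhibited(row$dose_uM, row$Ki_uM)
      params_i <- scale_activity(model$params,
                                 stats::setNames(1 - fi, row$target))
      model_i <- glycolysis_model(params_i)
    }
    init <- warm[[row$compound]] %||% base_init
    # long horizon: strong inhibition can relax very slowly toward extreme
    # (but genuine) steady states
    sol <- solve_steady_state(model_i, init = init, t_max = 3e4,
                              warm_start = !identical(init, base_init))
    if (sol$converged) warm[[row$compound]] <<- sol$state
    list(row = row, fi = fi, sol = sol)
  })

  purrr::map_dfr(solved, function(s) {
    purrr::map_dfr(seq_len(config$replicates), function(r) {
      base <- tibble::tibble(
        condition = s$row$condition, compound = s$row$compound,
        target = s$row$target, dose_uM = s$row$dose_uM,
        fraction_inhibited = s$fi, replicate = r,
        converged = s$sol$converged
      )
      if (!s$sol$converged) {
        conc <- stats::setNames(rep(NA_real_, length(SPECIES_INTRACELLULAR)),
                                paste0("conc_", SPECIES_INTRACELLULAR))
        return(dplyr::bind_cols(base, tibble::as_tibble(as.list(conc)),
                                tibble::tibble(J_Lac = NA_real_)))
      }
      conc <- s$sol$state[SPECIES_INTRACELLULAR]
      J <- s$sol$fluxes[["LDH"]]
      if (config$noise_sigma > 0) {
        noise <- exp(stats::rnorm(length(conc) + 1, 0, config$noise_sigma))
        conc <- conc * noise[-1]
        J <- J * noise[1]
      }
      dplyr::bind_cols(
        base,
        tibble::as_tibble(as.list(stats::setNames(
          conc, paste0("conc_", SPECIES_INTRACELLULAR)))),
        tibble::tibble(J_Lac = J)
      )
    })
  })
}

#' Generate a synthetic tracer time course
#'
#' Labeled lactate accumulating linearly, `intercept + true_flux * t`, with
#' seeded additive Gaussian noise, matching the media-collection design
#' (default sampling at 30/60/90/120 min).
#'
#' @param true_flux True accumulation slope (concentration per min).
#' @param times Sampling times in minutes.
#' @param noise_sigma Additive Gaussian noise sd (concentration units).
#' @param intercept Labeled lactate at time zero.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param condition,replicate Identifiers carried into the table.
#' @return Tibble: `condition`, `replicate`, `time_min`, `lactate_conc`.
#' @export
generate_tracer_timecourse <- function(true_flux, times = c(30, 60, 90, 120),
                                       noise_sigma = 0, intercept = 0,
                                       seed = NULL, condition = "cond",
                                       replicate = 1L) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    condition = condition, replicate = replicate, time_min = times,
    lactate_conc = intercept + true_flux * times +
      stats::rnorm(length(times), 0, noise_sigma)
  )
}

#' Simulate an in-silico dose-response panel for one step
#'
#' Computes the steady-state lactate flux at each residual-activity level of
#' the target step (noise-free), the in-silico mirror of the empirical FCC
#' experiment, used to cross-validate [empirical_fcc()] against
#' [compute_fcc()].
#'
#' @param model Baseline `glyco_model`.
#' @param target_step Step identifier to inhibit.
#' @param doses Dose vector (same units as `Ki`).
#' @param Ki Inhibition constant.
#' @return Tibble: `dose`, `fraction_inhibited`, `flux` (NA where a re-solve
#'   fails), `converged`. Doses are solved (by continuation from the previous
#'   dose) and returned in increasing order.
#' @export
simulate_dose_response <- function(model, target_step, doses, Ki) {
  if (length(doses) == 0) {
    return(tibble::tibble(dose = numeric(), fraction_inhibited = numeric(),
                          flux = numeric(), converged = logical()))
  }
  base_init <- initial_state(model$params)
  init <- base_init
  first <- TRUE
  purrr::map_dfr(doses[order(doses)], function(d) {
    fi <- fraction_inhibited(d, Ki)
    params_i <- scale_activity(model$params,
                               stats::setNames(1 - fi, target_step))
    sol <- solve_steady_state(glycolysis_model(params_i), init = init,
                              warm_start = !first)
    if (sol$converged) {
      init <<- sol$state
      first <<- FALSE
    }
    tibble::tibble(
      dose = d, fraction_inhibited = fi,
      flux = if (sol$converged) sol$fluxes[["LDH"]] else NA_real_,
      converged = sol$converged
    )
  })
}
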