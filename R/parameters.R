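# Curated default parameter set.
#
# The defaults are a literature-plausible reconstruction, not a published
# supplement: maximal rates are set a few-fold above the baseline pathway
# flux they must carry, Michaelis constants are typical reported values for
# mammalian enzymes, and standard Gibbs energies are textbook glycolysis
# values re-referenced to a 1 mM standard state (so mass-action ratios formed
# from mM concentrations compare directly with Keq). See the methods
# vignette for the calibration rationale.

#' Curated default kinetic parameter set
#'
#' Returns the reference parameterization of the glycolysis network: rate-law
#' constants for every reaction, standard Gibbs free energies (1 mM reference
#' state) for the Haldane construction, conserved-pool totals, media
#' concentrations and the cell:media volume ratio. The set is deterministic
#' and versioned with the package; it is a synthetic, literature-plausible
#' curation (no published per-reaction supplement is reproduced here).
#'
#' @param media_dynamic Logical; if `TRUE` media species follow their dilution
#'   dynamics instead of being clamped (used for tracer simulations).
#' @param ldh_mechanism `"random"` (default) or `"ordered"` bi-bi mechanism
#'   for LDH.
#' @return An object of class `glyco_params` (a structured list).
#' @examples
#' p <- default_parameter_set()
#' names(p$reactions)
#' @export
default_parameter_set <- function(media_dynamic = FALSE,
                                  ldh_mechanism = c("random", "ordered")) {
  ldh_mechanism <- match.arg(ldh_mechanism)
  reactions <- list(
    GTR = list(Jtrmax = 3.0, Km = 1.5),
    HK = list(Vf = 25, Kmf = 0.04, Kmr = 0.5, dG0 = -16.7, K_G6P = 0.1),
    PGI = list(Vf = 30, Kmf = 0.3, Kmr = 0.12, dG0 = 1.7),
    PFK = list(Vf = 40, Kmf = 0.02, Kmr = 1.0, dG0 = -14.2,
               K_F26BP = 0.005, K_AMP = 0.05, K_ATP = 2.0),
    PFK2 = list(Vf = 0.07, Kmf = 0.05, Kmr = 5.0, dG0 = -14.2),
    FBPASE2 = list(kcat = 2.5),
    ALD = list(Vf = 30, Kmf = 0.1, Kmr = 0.04, dG0 = 2.7),
    TPI = list(Vf = 120, Kmf = 0.5, Kmr = 0.05, dG0 = 7.5),
    GAPDH = list(Vf = 6, Km_gap = 0.1, Km_nad = 0.06, Km_pi = 1.5,
                 Km_bpg = 0.01, Km_nadh = 0.01,
                 Kmf = 0.009, Kmr = 1e-4, dG0 = 24.1),
    PGK = list(Vf = 150, Kmf = 2e-4, Kmr = 0.4, dG0 = -18.8),
    PGM = list(Vf = 120, Kmf = 0.5, Kmr = 0.08, dG0 = 4.4),
    ENO = list(Vf = 120, Kmf = 0.08, Kmr = 0.15, dG0 = -3.2),
    PK = list(Vf = 60, Kmf = 0.09, Kmr = 50, dG0 = -31.4, K_FBP = 0.2),
    LDH = list(Vf = 60, Km_pyr = 0.3, Km_nadh = 0.002, Km_lac = 10,
               Km_nad = 0.2, Kmf = 6e-4, Kmr = 2.0, dG0 = -25.1),
    MCT = list(Jtrmax = 20, Km = 2.0),
    OXPHOS = list(Vmax = 2.0, Km_pyr = 0.01, Km_o2 = 0.005, Km_pi = 0.8,
                  K_ADP = 0.05, atp_per_pyr = 12.5, o2_per_pyr = 3),
    CK = list(Vf = 40, Kmf = 0.4, Kmr = 6.0, dG0 = -12.5),
    AK = list(kcat = 100, Keq = 1),
    ATPASE = list(kcat = 3.2),
    PHGDH = list(Vf = 1.2, Km_pg3 = 0.5, Km_nad = 0.07, Km_ser = 1.5,
                 Km_nadh = 0.01, Kmf = 0.035, Kmr = 0.015, dG0 = -10),
    SERT = list(Jtrmax = 0.6, Km = 1.0),
    O2T = list(k = 30),
    PIT = list(k = 0.5, Pi_media = 5.0),
    MAS = list(Vmax = 2, Km_nadh = 0.01)
  )
  initial <- c(
    GLC = 1.0, G6P = 0.2, F6P = 0.06, FBP = 0.5, F26BP = 0.02,
    DHAP = 0.5, GAP = 0.05, BPG = 0.002, PG3 = 0.2, PG2 = 0.03,
    PEP = 0.08, PYR = 0.15, LAC = 3.0, SER = 1.0,
    ATP = 3.0, ADP = 0.3, AMP = 0.03, NAD = 0.5, NADH = 0.005,
    Pi = 5.0, Cr = 9.7, PCr = 0.8, O2 = 0.1
  )
  media <- c(GLC_e = 5.0, LAC_e = 1.0, O2_e = 0.2, SER_e = 0.3)
  pools <- c(
    adenylate = unname(initial[["ATP"]] + initial[["ADP"]] + initial[["AMP"]]),
    nad = unname(initial[["NAD"]] + initial[["NADH"]]),
    creatine = unname(initial[["Cr"]] + initial[["PCr"]])
  )
  structure(
    list(
      reactions = reactions,
      initial = initial,
      media = media,
      pools = pools,
      r_ie = 0.01,
      temperature = 310.15,
      media_dynamic = media_dynamic,
      ldh_mechanism = ldh_mechanism
    ),
    class = "glyco_params"
  )
}

#' @export
print.glyco_params <- function(x, ...) {
  cat("<glyco_params>", length(x$reactions), "reactions,",
      length(x$initial) + length(x$media), "species",
      sprintf("(T = %.2f K, r_ie = %g)\n", x$temperature, x$r_ie))
  invisible(x)
}

#' Flatten a parameter set to a tidy table
#'
#' One row per (reaction, parameter) pair, the plain tabular exchange format
#' for the model configuration.
#'
#' @param params A `glyco_params` object.
#' @return Tibble with columns `reaction`, `parameter`, `value`, `units`,
#'   `note`.
#' @export
parameter_table <- function(params = default_parameter_set()) {
  unit_of <- function(parameter) {
    dplyr::case_when(
      parameter %in% c("Vf", "Vmax", "Jtrmax") ~ "mM/hr",
      parameter == "kcat" ~ "1/hr (or 1/(mM hr) for AK)",
      parameter == "dG0" ~ "kJ/mol (1 mM reference state)",
      parameter %in% c("atp_per_pyr", "o2_per_pyr", "Keq") ~ "dimensionless",
      parameter == "k" ~ "1/hr",
      TRUE ~ "mM (lumped terms: mM^k)"
    )
  }
  rows <- purrr::imap_dfr(params$reactions, function(pl, rxn) {
    tibble::tibble(reaction = rxn, parameter = names(pl),
                   value = unlist(pl, use.names = FALSE))
  })
  extra <- tibble::tibble(
    reaction = c(rep("pool", 3), rep("media", 4), "global", "global"),
    parameter = c(names(params$pools), names(params$media),
                  "r_ie", "temperature"),
    value = c(unname(params$pools), unname(params$media),
              params$r_ie, params$temperature)
  )
  dplyr::bind_rows(rows, extra) |>
    dplyr::mutate(
      units = unit_of(.data$parameter),
      note = "curated default (literature-plausible synthetic reconstruction)"
    )
}

#' Read/write the parameter exchange table
#'
#' `write_parameter_table()` writes the tidy parameter table as TSV;
#' `read_parameter_table()` reads one back and applies it onto a template
#' parameter set.
#'
#' @param params A `glyco_params` object.
#' @param path File path of the TSV.
#' @param template Parameter set providing the structure to fill.
#' @return `read_parameter_table()` returns a `glyco_params`;
#'   `write_parameter_table()` returns `path` invisibly.
#' @export
write_parameter_table <- function(params, path) {
  utils::write.table(parameter_table(params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path, template = default_parameter_set()) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  p <- template
  for (i in seq_len(nrow(tab))) {
    rxn <- tab$reaction[i]; par <- tab$parameter[i]; val <- tab$value[i]
    if (rxn == "pool") {
      p$pools[[par]] <- val
    } else if (rxn == "media") {
      p$media[[par]] <- val
    } else if (rxn == "global") {
      if (par == "r_ie") p$r_ie <- val else p$temperature <- val
    } else {
      p$reactions[[rxn]][[par]] <- val
    }
  }
  p
}

# The capacity ("enzyme expression") parameter of each step, i.e. what a
# Vmax draw or an FCC perturbation rescales.
activity_parameter <- function(step) {
  switch(step,
    GTR = "Jtrmax", MCT = "Jtrmax", SERT = "Jtrmax", O2T = "k", PIT = "k",
    OXPHOS = "Vmax", MAS = "Vmax", FBPASE2 = "kcat", AK = "kcat",
    ATPASE = "kcat",
    "Vf"
  )
}

#' Rescale the activity of one or more steps
#'
#' Multiplies the capacity parameter (Vmax, transport maximum, or first-order
#' rate constant) of the named steps by the given factors. Haldane-consistent
#' reverse rates scale along with the forward rates, so thermodynamic
#' consistency is preserved.
#'
#' @param params A `glyco_params` object.
#' @param factors Named numeric vector of multiplicative factors, names are
#'   step identifiers from [CONTROLLABLE_STEPS].
#' @return A modified `glyco_params`.
#' @export
scale_activity <- function(params, factors) {
  bad <- setdiff(names(factors), CONTROLLABLE_STEPS)
  if (length(bad)) {
    stop("unknown steps: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (step in names(factors)) {
    par <- activity_parameter(step)
    params$reactions[[step]][[par]] <-
      params$reactions[[step]][[par]] * factors[[step]]
  }
  params
}

#' Baseline activity (capacity) values of the controllable steps
#'
#' @param params A `glyco_params` object.
#' @param steps Character vector of step identifiers.
#' @return Named numeric vector of capacities (mM/hr or 1/hr).
#' @export
step_activities <- function(params, steps = CONTROLLABLE_STEPS) {
  vapply(steps, function(s) params$reactions[[s]][[activity_parameter(s)]],
         numeric(1))
}

#' Controllable steps of the reference network
#'
#' Character vector of every enzyme/transport capacity that can be rescaled,
#' sampled in the ensemble, or perturbed in the control analysis (all
#' reactions except the algebraically slaved NADH shuttle).
#'
#' @format Character vector of step identifiers.
#' @export
CONTROLLABLE_STEPS <- CONTROLLABLE_STEPS
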