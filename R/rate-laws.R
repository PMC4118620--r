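#' Equilibrium constant from standard Gibbs free energy
#'
#' Converts a standard reaction Gibbs free energy (kJ/mol) into the apparent
#' equilibrium constant via `Keq = exp(-dG0 / (R * T))`, with
#' `R = 8.314e-3 kJ/(mol K)`.
#'
#' @param dG0 Standard reaction Gibbs free energy in kJ/mol.
#' @param temperature Absolute temperature in Kelvin (default 310.15, i.e. 37 C).
#' @return Dimensionless equilibrium constant (strictly positive).
#' @examples
#' keq_from_gibbs(0)                    # 1
#' keq_from_gibbs(-16.7)                # hexokinase-like, strongly forward
#' @export
keq_from_gibbs <- function(dG0, temperature = 310.15) {
  if (!all(is.finite(dG0))) {
    stop("`dG0` must be finite", call. = FALSE)
  }
  if (any(temperature <= 0)) {
    stop("`temperature` must be positive", call. = FALSE)
  }
  exp(-dG0 / (GAS_CONSTANT_KJ * temperature))
}

# kJ/(mol K)
GAS_CONSTANT_KJ <- 8.314e-3

#' Reverse Vmax from the Haldane relationship
#'
#' For a reversible enzyme the forward and reverse maximal rates are not
#' independent: thermodynamic consistency requires
#' `Vrmax = Vfmax * Kmr / (Kmf * Keq)`. Constructing every reversible rate law
#' through this relation guarantees that the net rate vanishes exactly at
#' chemical equilibrium and always points down the free-energy gradient.
#'
#' @param Vfmax Forward maximal rate (mM/hr).
#' @param Kmf,Kmr Lumped forward/reverse binding constants (mM^k for a
#'   k-ligand lumped term).
#' @param Keq Equilibrium constant (dimensionless, > 0).
#' @return Reverse maximal rate (mM/hr).
#' @export
haldane_reverse_vmax <- function(Vfmax, Kmf, Kmr, Keq) {
  if (any(!is.finite(c(Vfmax, Kmf, Kmr, Keq))) ||
      any(c(Kmf, Kmr, Keq) <= 0) || any(Vfmax < 0)) {
    stop("Haldane relation requires Vfmax >= 0 and Kmf, Kmr, Keq > 0",
         call. = FALSE)
  }
  Vfmax * Kmr / (Kmf * Keq)
}

#' Allosteric control function
#'
#' Multiplicative regulation factor: each activator contributes
#' `[A] / ([A] + K_A)`, each inhibitor `K_I / ([I] + K_I)`. An empty regulator
#' list returns 1 (unregulated flux).
#'
#' @param conc Numeric vector of regulator concentrations (mM, >= 0).
#' @param K Numeric vector of activation/inhibition constants (mM, > 0).
#' @param mode Character vector, each `"activator"` or `"inhibitor"`.
#' @return Multiplier in (0, Inf) (in practice (0, 1]).
#' @examples
#' control_function(1, 1, "activator")   # half-saturation: 0.5
#' control_function(numeric(), numeric(), character())  # 1
#' @export
control_function <- function(conc, K, mode) {
  if (length(conc) == 0L) return(1)
  stopifnot(length(conc) == length(K), length(conc) == length(mode))
  if (any(conc < 0) || any(K <= 0)) {
    stop("regulator concentrations must be >= 0 and constants > 0",
         call. = FALSE)
  }
  terms <- ifelse(mode == "activator", conc / (conc + K), K / (conc + K))
  prod(terms)
}

#' Reversible one-step binding rate law
#'
#' Reduced reversible mechanism with lumped substrate and product binding:
#' `chi * (Vfmax * S - Vrmax * P) / (1 + S + P)` where `S = prod(Cs^nu)/Kmf`
#' and `P = prod(Cp^nu)/Kmr` are the dimensionless lumped terms supplied by
#' the caller.
#'
#' @param substrate_term Dimensionless lumped substrate term (>= 0).
#' @param product_term Dimensionless lumped product term (>= 0).
#' @param Vfmax,Vrmax Forward/reverse maximal rates (mM/hr); `Vrmax` should be
#'   Haldane-consistent for reversible reactions.
#' @param chi Allosteric multiplier (default 1).
#' @return Net rate in mM/hr; positive means net forward.
#' @export
rate_one_step <- function(substrate_term, product_term, Vfmax, Vrmax, chi = 1) {
  chi * (Vfmax * substrate_term - Vrmax * product_term) /
    (1 + substrate_term + product_term)
}

#' Random bi-bi reversible rate law
#'
#' Two-substrate two-product mechanism with random ligand binding order
#' (used for LDH and PHGDH). The denominator carries every single-ligand
#' term plus the two lumped binary terms.
#'
#' @param S1,S2,P1,P2 Ligand concentrations (mM).
#' @param Vfmax,Vrmax Maximal rates (mM/hr).
#' @param Kmf,Kmr Lumped binary binding constants (mM^2).
#' @param Km_S1,Km_S2,Km_P1,Km_P2 Single-ligand Michaelis constants (mM).
#' @param chi Allosteric multiplier (default 1).
#' @return Net rate (mM/hr).
#' @export
rate_random_bibi <- function(S1, S2, P1, P2, Vfmax, Vrmax, Kmf, Kmr,
                             Km_S1, Km_S2, Km_P1, Km_P2, chi = 1) {
  num <- Vfmax * S1 * S2 / Kmf - Vrmax * P1 * P2 / Kmr
  den <- 1 + S1 / Km_S1 + S2 / Km_S2 + S1 * S2 / Kmf +
    P1 / Km_P1 + P2 / Km_P2 + P1 * P2 / Kmr
  chi * num / den
}

#' Ordered bi-bi reversible rate law
#'
#' As [rate_random_bibi()] but with ordered ligand binding (cofactor first):
#' the denominator lacks the lone `S1` and lone `P1` terms. For identical
#' parameters its denominator is never larger than the random form's, so the
#' ordered rate is at least as large in magnitude.
#'
#' @inheritParams rate_random_bibi
#' @return Net rate (mM/hr).
#' @export
rate_ordered_bibi <- function(S1, S2, P1, P2, Vfmax, Vrmax, Kmf, Kmr,
                              Km_S1, Km_S2, Km_P1, Km_P2, chi = 1) {
  num <- Vfmax * S1 * S2 / Kmf - Vrmax * P1 * P2 / Kmr
  den <- 1 + S2 / Km_S2 + S1 * S2 / Kmf +
    P2 / Km_P2 + P1 * P2 / Kmr
  chi * num / den
}

#' Random ter-bi reversible rate law (GAPDH form)
#'
#' Three-substrate two-product generalization of the random bi-bi mechanism,
#' used for GAPDH (GAP + NAD+ + Pi <-> 1,3-BPG + NADH). The denominator
#' carries 1, each single-ligand term, the full forward ternary term and the
#' full reverse binary term.
#'
#' @param S1,S2,S3 Substrate concentrations (mM): GAP, NAD+, Pi.
#' @param P1,P2 Product concentrations (mM): BPG, NADH.
#' @param Vfmax,Vrmax Maximal rates (mM/hr).
#' @param Kmf Lumped ternary forward constant (mM^3).
#' @param Kmr Lumped binary reverse constant (mM^2).
#' @param Km_S1,Km_S2,Km_S3,Km_P1,Km_P2 Single-ligand constants (mM).
#' @param chi Allosteric multiplier (default 1).
#' @return Net rate (mM/hr).
#' @export
rate_ter_bi <- function(S1, S2, S3, P1, P2, Vfmax, Vrmax, Kmf, Kmr,
                        Km_S1, Km_S2, Km_S3, Km_P1, Km_P2, chi = 1) {
  num <- Vfmax * S1 * S2 * S3 / Kmf - Vrmax * P1 * P2 / Kmr
  den <- 1 + S1 / Km_S1 + S2 / Km_S2 + S3 / Km_S3 + S1 * S2 * S3 / Kmf +
    P1 / Km_P1 + P2 / Km_P2 + P1 * P2 / Kmr
  chi * num / den
}

#' Facilitated (carrier-mediated) transport flux
#'
#' Net influx across the membrane for a carrier with symmetric affinity:
#' `Jtrmax * (Ce - Ci) / Km / (1 + Ce/Km + Ci/Km)`. Antisymmetric under
#' swapping the two compartments; saturates at `Jtrmax`.
#'
#' @param Ce,Ci Extracellular / intracellular concentrations (mM).
#' @param Jtrmax Maximal transport rate (mM/hr).
#' @param Km_tr Transport Michaelis constant (mM).
#' @return Net influx into the cell (mM/hr); negative means efflux.
#' @export
transport_facilitated <- function(Ce, Ci, Jtrmax, Km_tr) {
  Jtrmax * (Ce / Km_tr - Ci / Km_tr) / (1 + Ce / Km_tr + Ci / Km_tr)
}

#' Passive diffusion flux (oxygen)
#'
#' Linear net influx `k * (Ce - Ci)`.
#'
#' @param Ce,Ci Extracellular / intracellular concentrations (mM).
#' @param k_O2 Effective first-order permeation constant (1/hr).
#' @return Net influx (mM/hr).
#' @export
transport_passive <- function(Ce, Ci, k_O2) {
  k_O2 * (Ce - Ci)
}

#' Mitochondrial NADH shuttle balance
#'
#' Steady-state balance of the malate-aspartate / glycerol-3-phosphate
#' shuttle: the shuttle must re-oxidize exactly the cytosolic NADH that LDH
#' does not, which by pathway stoichiometry equals
#' `V_mas = V_ox + 2 * V_phgdh`. In the dynamic model the shuttle is a
#' saturable kinetic capacity; this identity emerges at any steady state and
#' is used as a consistency check.
#'
#' @param V_ox Mitochondrial pyruvate oxidation flux (mM/hr).
#' @param V_phgdh PHGDH (serine branch) flux (mM/hr).
#' @return Shuttle flux (mM/hr).
#' @export
shuttle_flux <- function(V_ox, V_phgdh) {
  V_ox + 2 * V_phgdh
}
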