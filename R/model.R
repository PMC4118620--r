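# Reference network: species bookkeeping and ODE assembly.
#
# The state vector carries 27 time-dependent concentrations (mM): 23
# intracellular species and 4 media species. Media species are clamped
# (boundary-constant) by default; a config switch turns on their dilution
# dynamics (dCe/dt scaled by the cell:media volume ratio) for tracer
# simulations. Three mass conservation laws (adenylates, pyridine
# nucleotides, creatine) are built into the stoichiometry.

SPECIES_INTRACELLULAR <- c(
  "GLC", "G6P", "F6P", "FBP", "F26BP", "DHAP", "GAP", "BPG", "PG3", "PG2",
  "PEP", "PYR", "LAC", "SER", "ATP", "ADP", "AMP", "NAD", "NADH", "Pi",
  "Cr", "PCr", "O2"
)
SPECIES_MEDIA <- c("GLC_e", "LAC_e", "O2_e", "SER_e")
SPECIES_ALL <- c(SPECIES_INTRACELLULAR, SPECIES_MEDIA)

REACTION_NAMES <- c(
  "GTR", "HK", "PGI", "PFK", "PFK2", "FBPASE2", "ALD", "TPI", "GAPDH",
  "PGK", "PGM", "ENO", "PK", "LDH", "MCT", "OXPHOS", "CK", "AK", "ATPASE",
  "PHGDH", "SERT", "O2T", "PIT", "MAS"
)

# Every enzyme/transport capacity is a controllable step, including the
# mitochondrial NADH shuttle (modeled as a saturable capacity; at steady
# state its flux equals the Eq-style balance V_ox + 2 V_phgdh, see
# shuttle_flux()).
CONTROLLABLE_STEPS <- REACTION_NAMES

GLYCOLYTIC_ENZYMES <- c("HK", "PGI", "PFK", "ALD", "TPI", "GAPDH",
                        "PGK", "PGM", "ENO", "PK")

#' Species table of the reference glycolysis model
#'
#' @param params A parameter set from [default_parameter_set()] (used for the
#'   initial concentrations).
#' @return A tibble with one row per state variable: `name`, `compartment`
#'   (`"cell"` or `"media"`), `role` (`"dynamic"` or `"boundary-constant"`),
#'   and `initial_concentration` (mM).
#' @export
species_table <- function(params = default_parameter_set()) {
  init <- initial_state(params)
  media_dynamic <- isTRUE(params$media_dynamic)
  tibble::tibble(
    name = SPECIES_ALL,
    compartment = rep(c("cell", "media"),
                      c(length(SPECIES_INTRACELLULAR), length(SPECIES_MEDIA))),
    role = ifelse(.data$compartment == "cell" | media_dynamic,
                  "dynamic", "boundary-constant"),
    initial_concentration = unname(init[SPECIES_ALL])
  )
}

#' Reaction specifications of the reference network
#'
#' Declarative list of the model's reactions: mechanism, substrates/products
#' with stoichiometric coefficients, and allosteric regulators. This is the
#' bookkeeping view of the network; the rate laws themselves are evaluated by
#' [model_fluxes()].
#'
#' @return Named list of reaction specs.
#' @export
reaction_specs <- function() {
  r <- function(mechanism, substrates, products, regulators = NULL) {
    list(mechanism = mechanism, substrates = substrates, products = products,
         regulators = regulators)
  }
  list(
    GTR     = r("facilitated_transport", c(GLC_e = 1), c(GLC = 1)),
    HK      = r("one_step", c(GLC = 1, ATP = 1), c(G6P = 1, ADP = 1),
                list(G6P = list(K = NA, mode = "inhibitor"))),
    PGI     = r("one_step", c(G6P = 1), c(F6P = 1)),
    PFK     = r("one_step", c(F6P = 1, ATP = 1), c(FBP = 1, ADP = 1),
                list(F26BP = list(K = NA, mode = "activator"),
                     AMP = list(K = NA, mode = "activator"),
                     ATP = list(K = NA, mode = "inhibitor"))),
    PFK2    = r("one_step", c(F6P = 1, ATP = 1), c(F26BP = 1, ADP = 1)),
    FBPASE2 = r("mass_action", c(F26BP = 1), c(F6P = 1, Pi = 1)),
    ALD     = r("one_step", c(FBP = 1), c(DHAP = 1, GAP = 1)),
    TPI     = r("one_step", c(DHAP = 1), c(GAP = 1)),
    GAPDH   = r("ter_bi", c(GAP = 1, NAD = 1, Pi = 1), c(BPG = 1, NADH = 1)),
    PGK     = r("one_step", c(BPG = 1, ADP = 1), c(PG3 = 1, ATP = 1)),
    PGM     = r("one_step", c(PG3 = 1), c(PG2 = 1)),
    ENO     = r("one_step", c(PG2 = 1), c(PEP = 1)),
    PK      = r("one_step", c(PEP = 1, ADP = 1), c(PYR = 1, ATP = 1),
                list(FBP = list(K = NA, mode = "activator"))),
    LDH     = r("random_bibi", c(PYR = 1, NADH = 1), c(LAC = 1, NAD = 1)),
    MCT     = r("facilitated_transport", c(LAC_e = 1), c(LAC = 1)),
    OXPHOS  = r("oxphos", c(PYR = 1, O2 = 3, ADP = 12.5, Pi = 12.5),
                c(ATP = 12.5),
                list(ADP = list(K = NA, mode = "activator"))),
    CK      = r("one_step", c(PCr = 1, ADP = 1), c(Cr = 1, ATP = 1)),
    AK      = r("mass_action", c(ADP = 2), c(ATP = 1, AMP = 1)),
    ATPASE  = r("mass_action", c(ATP = 1), c(ADP = 1, Pi = 1)),
    PHGDH   = r("random_bibi", c(PG3 = 1, NAD = 1),
                c(SER = 1, NADH = 1, Pi = 1)),
    SERT    = r("facilitated_transport", c(SER_e = 1), c(SER = 1)),
    O2T     = r("passive_transport", c(O2_e = 1), c(O2 = 1)),
    # inorganic-phosphate exchange with the media; the extracellular side is
    # an implicit fixed boundary (parameter Pi_media), so no state is added.
    # Without it total phosphate would be a fourth, spurious conservation law
    # and steady states would be non-isolated.
    PIT     = r("boundary_exchange", stats::setNames(numeric(0), character(0)),
                c(Pi = 1)),
    # cytosolic NADH re-oxidation by the malate-aspartate / G3P shuttles,
    # saturable in NADH; at steady state its flux balances to
    # V_ox + 2 V_phgdh by stoichiometry
    MAS     = r("shuttle", c(NADH = 1), c(NAD = 1))
  )
}

# Transport reactions move one unit into the cell per unit flux; the matching
# media change is scaled by the cell:media volume ratio r_ie.
TRANSPORT_MEDIA_SPECIES <- c(GTR = "GLC_e", MCT = "LAC_e",
                             SERT = "SER_e", O2T = "O2_e")

#' Stoichiometric matrix of the reference network
#'
#' @param params Parameter set (supplies the volume ratio `r_ie` and the
#'   media-dynamics switch).
#' @return Matrix (27 species x 23 reactions). Media rows carry `-r_ie` for
#'   their transport reaction when media dynamics are enabled, and 0 when the
#'   media are boundary-constant.
#' @export
stoichiometry_matrix <- function(params = default_parameter_set()) {
  specs <- reaction_specs()
  S <- matrix(0, nrow = length(SPECIES_ALL), ncol = length(specs),
              dimnames = list(SPECIES_ALL, names(specs)))
  for (j in names(specs)) {
    sp <- specs[[j]]
    for (s in names(sp$substrates)) {
      if (s %in% SPECIES_INTRACELLULAR) {
        S[s, j] <- S[s, j] - sp$substrates[[s]]
      }
    }
    for (p in names(sp$products)) {
      if (p %in% SPECIES_INTRACELLULAR) {
        S[p, j] <- S[p, j] + sp$products[[p]]
      }
    }
  }
  if (isTRUE(params$media_dynamic)) {
    for (j in names(TRANSPORT_MEDIA_SPECIES)) {
      S[TRANSPORT_MEDIA_SPECIES[[j]], j] <- -params$r_ie
    }
  }
  S
}

#' Assemble the reference model
#'
#' Bundles the parameter set, species/reaction bookkeeping, stoichiometric
#' matrix and precomputed kinetic constants (equilibrium constants from
#' standard Gibbs energies and Haldane-consistent reverse Vmax values) into
#' one object used by the integrator, the ensemble sampler and the control
#' analysis. The flux evaluator is compiled once into a closure over the
#' numeric constants so the ODE right-hand side is pure arithmetic.
#'
#' @param params Parameter set, see [default_parameter_set()].
#' @return An object of class `glyco_model`.
#' @export
glycolysis_model <- function(params = default_parameter_set()) {
  stopifnot(inherits(params, "glyco_params"))
  kin <- build_kinetics(params)
  S <- stoichiometry_matrix(params)
  structure(
    list(
      params = params,
      kinetics = kin,
      species = species_table(params),
      reactions = reaction_specs(),
      S = S,
      S_num = unname(S),
      flux_fun = build_flux_fun(params, kin)
    ),
    class = "glyco_model"
  )
}

# Compile the rate laws into a closure of plain arithmetic over the state
# vector in SPECIES_ALL order. State indices:
#  1 GLC   2 G6P   3 F6P   4 FBP   5 F26BP  6 DHAP  7 GAP   8 BPG
#  9 PG3  10 PG2  11 PEP  12 PYR  13 LAC   14 SER  15 ATP  16 ADP
# 17 AMP  18 NAD  19 NADH 20 Pi   21 Cr    22 PCr  23 O2
# 24 GLC_e 25 LAC_e 26 O2_e 27 SER_e
# Flux order matches REACTION_NAMES.
build_flux_fun <- function(params, kin = build_kinetics(params)) {
  ordered_ldh <- identical(params$ldh_mechanism, "ordered")
  gtr_J <- kin$GTR$Jtrmax; gtr_K <- kin$GTR$Km
  hk_Vf <- kin$HK$Vf; hk_Vr <- kin$HK$Vr; hk_Kmf <- kin$HK$Kmf
  hk_Kmr <- kin$HK$Kmr; hk_KG6P <- kin$HK$K_G6P
  pgi_Vf <- kin$PGI$Vf; pgi_Vr <- kin$PGI$Vr
  pgi_Kmf <- kin$PGI$Kmf; pgi_Kmr <- kin$PGI$Kmr
  pfk_Vf <- kin$PFK$Vf; pfk_Vr <- kin$PFK$Vr; pfk_Kmf <- kin$PFK$Kmf
  pfk_Kmr <- kin$PFK$Kmr; pfk_KF26 <- kin$PFK$K_F26BP
  pfk_KAMP <- kin$PFK$K_AMP; pfk_KATP <- kin$PFK$K_ATP
  pfk2_Vf <- kin$PFK2$Vf; pfk2_Vr <- kin$PFK2$Vr
  pfk2_Kmf <- kin$PFK2$Kmf; pfk2_Kmr <- kin$PFK2$Kmr
  fbp2_k <- kin$FBPASE2$kcat
  ald_Vf <- kin$ALD$Vf; ald_Vr <- kin$ALD$Vr
  ald_Kmf <- kin$ALD$Kmf; ald_Kmr <- kin$ALD$Kmr
  tpi_Vf <- kin$TPI$Vf; tpi_Vr <- kin$TPI$Vr
  tpi_Kmf <- kin$TPI$Kmf; tpi_Kmr <- kin$TPI$Kmr
  g_Vf <- kin$GAPDH$Vf; g_Vr <- kin$GAPDH$Vr
  g_Kmf <- kin$GAPDH$Kmf; g_Kmr <- kin$GAPDH$Kmr
  g_Kgap <- kin$GAPDH$Km_gap; g_Knad <- kin$GAPDH$Km_nad
  g_Kpi <- kin$GAPDH$Km_pi; g_Kbpg <- kin$GAPDH$Km_bpg
  g_Knadh <- kin$GAPDH$Km_nadh
  pgk_Vf <- kin$PGK$Vf; pgk_Vr <- kin$PGK$Vr
  pgk_Kmf <- kin$PGK$Kmf; pgk_Kmr <- kin$PGK$Kmr
  pgm_Vf <- kin$PGM$Vf; pgm_Vr <- kin$PGM$Vr
  pgm_Kmf <- kin$PGM$Kmf; pgm_Kmr <- kin$PGM$Kmr
  eno_Vf <- kin$ENO$Vf; eno_Vr <- kin$ENO$Vr
  eno_Kmf <- kin$ENO$Kmf; eno_Kmr <- kin$ENO$Kmr
  pk_Vf <- kin$PK$Vf; pk_Vr <- kin$PK$Vr; pk_Kmf <- kin$PK$Kmf
  pk_Kmr <- kin$PK$Kmr; pk_KFBP <- kin$PK$K_FBP
  l_Vf <- kin$LDH$Vf; l_Vr <- kin$LDH$Vr; l_Kmf <- kin$LDH$Kmf
  l_Kmr <- kin$LDH$Kmr; l_Kpyr <- kin$LDH$Km_pyr
  l_Knadh <- kin$LDH$Km_nadh; l_Klac <- kin$LDH$Km_lac
  l_Knad <- kin$LDH$Km_nad
  mct_J <- kin$MCT$Jtrmax; mct_K <- kin$MCT$Km
  ox_V <- kin$OXPHOS$Vmax; ox_Kpyr <- kin$OXPHOS$Km_pyr
  ox_Ko2 <- kin$OXPHOS$Km_o2; ox_Kpi <- kin$OXPHOS$Km_pi
  ox_KADP <- kin$OXPHOS$K_ADP
  ck_Vf <- kin$CK$Vf; ck_Vr <- kin$CK$Vr
  ck_Kmf <- kin$CK$Kmf; ck_Kmr <- kin$CK$Kmr
  ak_k <- kin$AK$kcat; ak_Keq <- kin$AK$Keq
  atpase_k <- kin$ATPASE$kcat
  ph_Vf <- kin$PHGDH$Vf; ph_Vr <- kin$PHGDH$Vr
  ph_Kmf <- kin$PHGDH$Kmf; ph_Kmr <- kin$PHGDH$Kmr
  ph_Kpg3 <- kin$PHGDH$Km_pg3; ph_Knad <- kin$PHGDH$Km_nad
  ph_Kser <- kin$PHGDH$Km_ser; ph_Knadh <- kin$PHGDH$Km_nadh
  sert_J <- kin$SERT$Jtrmax; sert_K <- kin$SERT$Km
  o2t_k <- kin$O2T$k
  pit_k <- kin$PIT$k; pit_Pme <- kin$PIT$Pi_media
  mas_V <- kin$MAS$Vmax; mas_K <- kin$MAS$Km_nadh

  function(y) {
    v <- numeric(24L)

    s <- y[24] / gtr_K; p <- y[1] / gtr_K
    v[1] <- gtr_J * (s - p) / (1 + s + p)

    chi <- hk_KG6P / (y[2] + hk_KG6P)
    s <- y[1] * y[15] / hk_Kmf; p <- y[2] * y[16] / hk_Kmr
    v[2] <- chi * (hk_Vf * s - hk_Vr * p) / (1 + s + p)

    s <- y[2] / pgi_Kmf; p <- y[3] / pgi_Kmr
    v[3] <- (pgi_Vf * s - pgi_Vr * p) / (1 + s + p)

    chi <- (y[5] / (y[5] + pfk_KF26)) * (y[17] / (y[17] + pfk_KAMP)) *
      (pfk_KATP / (y[15] + pfk_KATP))
    s <- y[3] * y[15] / pfk_Kmf; p <- y[4] * y[16] / pfk_Kmr
    v[4] <- chi * (pfk_Vf * s - pfk_Vr * p) / (1 + s + p)

    s <- y[3] * y[15] / pfk2_Kmf; p <- y[5] * y[16] / pfk2_Kmr
    v[5] <- (pfk2_Vf * s - pfk2_Vr * p) / (1 + s + p)

    v[6] <- fbp2_k * y[5]

    s <- y[4] / ald_Kmf; p <- y[6] * y[7] / ald_Kmr
    v[7] <- (ald_Vf * s - ald_Vr * p) / (1 + s + p)

    s <- y[6] / tpi_Kmf; p <- y[7] / tpi_Kmr
    v[8] <- (tpi_Vf * s - tpi_Vr * p) / (1 + s + p)

    sf <- y[7] * y[18] * y[20] / g_Kmf; pr <- y[8] * y[19] / g_Kmr
    v[9] <- (g_Vf * sf - g_Vr * pr) /
      (1 + y[7] / g_Kgap + y[18] / g_Knad + y[20] / g_Kpi + sf +
         y[8] / g_Kbpg + y[19] / g_Knadh + pr)

    s <- y[8] * y[16] / pgk_Kmf; p <- y[9] * y[15] / pgk_Kmr
    v[10] <- (pgk_Vf * s - pgk_Vr * p) / (1 + s + p)

    s <- y[9] / pgm_Kmf; p <- y[10] / pgm_Kmr
    v[11] <- (pgm_Vf * s - pgm_Vr * p) / (1 + s + p)

    s <- y[10] / eno_Kmf; p <- y[11] / eno_Kmr
    v[12] <- (eno_Vf * s - eno_Vr * p) / (1 + s + p)

    chi <- y[4] / (y[4] + pk_KFBP)
    s <- y[11] * y[16] / pk_Kmf; p <- y[12] * y[15] / pk_Kmr
    v[13] <- chi * (pk_Vf * s - pk_Vr * p) / (1 + s + p)

    sf <- y[12] * y[19] / l_Kmf; pr <- y[13] * y[18] / l_Kmr
    den <- if (ordered_ldh) {
      1 + y[19] / l_Knadh + sf + y[18] / l_Knad + pr
    } else {
      1 + y[12] / l_Kpyr + y[19] / l_Knadh + sf +
        y[13] / l_Klac + y[18] / l_Knad + pr
    }
    v[14] <- (l_Vf * sf - l_Vr * pr) / den

    s <- y[25] / mct_K; p <- y[13] / mct_K
    v[15] <- mct_J * (s - p) / (1 + s + p)

    v[16] <- ox_V * (y[12] / (y[12] + ox_Kpyr)) * (y[23] / (y[23] + ox_Ko2)) *
      (y[20] / (y[20] + ox_Kpi)) * (y[16] / (y[16] + ox_KADP))

    s <- y[22] * y[16] / ck_Kmf; p <- y[21] * y[15] / ck_Kmr
    v[17] <- (ck_Vf * s - ck_Vr * p) / (1 + s + p)

    v[18] <- ak_k * (y[16] * y[16] - y[15] * y[17] / ak_Keq)

    v[19] <- atpase_k * y[15]

    sf <- y[9] * y[18] / ph_Kmf; pr <- y[14] * y[19] / ph_Kmr
    v[20] <- (ph_Vf * sf - ph_Vr * pr) /
      (1 + y[9] / ph_Kpg3 + y[18] / ph_Knad + sf +
         y[14] / ph_Kser + y[19] / ph_Knadh + pr)

    s <- y[27] / sert_K; p <- y[14] / sert_K
    v[21] <- sert_J * (s - p) / (1 + s + p)

    v[22] <- o2t_k * (y[26] - y[23])

    v[23] <- pit_k * (pit_Pme - y[20])

    v[24] <- mas_V * y[19] / (y[19] + mas_K)

    v
  }
}

#' @export
print.glyco_model <- function(x, ...) {
  n_dyn <- sum(x$species$role == "dynamic")
  cat("<glyco_model> kinetic model of aerobic glycolysis\n")
  cat("  state variables:", nrow(x$species),
      sprintf("(%d dynamic, %d boundary-constant)\n",
              n_dyn, nrow(x$species) - n_dyn))
  cat("  reactions:", length(x$reactions),
      sprintf("(%d controllable steps)\n", length(CONTROLLABLE_STEPS)))
  cat("  conserved pools: adenylate =", x$params$pools[["adenylate"]],
      "mM, NAD(H) =", x$params$pools[["nad"]],
      "mM, creatine =", x$params$pools[["creatine"]], "mM\n")
  invisible(x)
}

# Precompute Keq and Haldane-consistent reverse capacities once per parameter
# set so the RHS evaluates only arithmetic.
build_kinetics <- function(params) {
  rx <- params$reactions
  Tk <- params$temperature
  k <- rx
  for (nm in names(k)) {
    p <- k[[nm]]
    if (!is.null(p$dG0)) {
      p$Keq <- keq_from_gibbs(p$dG0, Tk)
      p$Vr <- haldane_reverse_vmax(p$Vf, p$Kmf, p$Kmr, p$Keq)
    }
    k[[nm]] <- p
  }
  k
}

#' Initial (baseline) state of the model
#'
#' @param params Parameter set.
#' @return Named numeric vector of 27 concentrations (mM).
#' @export
initial_state <- function(params = default_parameter_set()) {
  c(params$initial, params$media)[SPECIES_ALL]
}

#' Evaluate all reaction fluxes at a state
#'
#' Computes the net rate of every reaction (mM/hr, positive = forward as
#' written in [reaction_specs()]) at the given state. Concentrations are
#' floored at zero before evaluation so transient small negatives from the
#' integrator never produce spurious reverse fluxes; every denominator is
#' `1 + nonnegative terms`, so all-zero states return zero rates.
#'
#' @param model A `glyco_model`.
#' @param state Named numeric vector over the 27 species (mM).
#' @return Named numeric vector of fluxes (mM/hr, one per reaction), including the algebraic
#'   shuttle flux `MAS = OXPHOS + 2 * PHGDH`.
#' @export
model_fluxes <- function(model, state) {
  y <- pmax(unname(state[SPECIES_ALL]), 0)
  v <- model$flux_fun(y)
  names(v) <- REACTION_NAMES
  v
}

#' Assemble the ODE right-hand side
#'
#' Derivatives (mM/hr) for all 27 state variables: stoichiometric sums of the
#' reaction fluxes for intracellular species, volume-ratio-scaled transport
#' for media species when media dynamics are enabled, and exactly zero for
#' boundary-constant media species. The three conserved pools (adenylates,
#' NAD(H), creatine) have analytically zero time derivative for any state.
#'
#' @param model A `glyco_model`.
#' @param state Named numeric vector of 27 concentrations (mM).
#' @return Named numeric vector of derivatives (mM/hr).
#' @export
model_odes <- function(model, state) {
  if (length(state) != length(SPECIES_ALL)) {
    stop("state must have length ", length(SPECIES_ALL),
         " (one entry per declared species)", call. = FALSE)
  }
  v <- model_fluxes(model, state)
  d <- drop(model$S %*% v)
  names(d) <- SPECIES_ALL
  d
}

# deSolve-compatible closure over the model.
make_rhs <- function(model) {
  S <- model$S_num
  flux <- model$flux_fun
  function(t, y, parms) {
    if (any(y < 0)) y[y < 0] <- 0
    list(S %*% flux(y))
  }
}

#' Conserved pool totals at a state
#'
#' @param state Named numeric state vector.
#' @return Named numeric vector: `adenylate` (ATP+ADP+AMP), `nad`
#'   (NAD+NADH), `creatine` (Cr+PCr), all mM.
#' @export
pool_totals <- function(state) {
  c(adenylate = unname(state[["ATP"]] + state[["ADP"]] + state[["AMP"]]),
    nad = unname(state[["NAD"]] + state[["NADH"]]),
    creatine = unname(state[["Cr"]] + state[["PCr"]]))
}

#' Mass-action ratio and equilibrium constant per reversible reaction
#'
#' For every Haldane-constrained reaction, returns the mass-action ratio
#' `Gamma` implied by its rate law's lumped substrate/product terms and the
#' equilibrium constant, so thermodynamic sign consistency
#' (`sign(rate) == sign(1 - Gamma/Keq)`) can be audited at any state.
#'
#' @param model A `glyco_model`.
#' @param state Named state vector (mM).
#' @return Tibble: `reaction`, `gamma`, `Keq`, `net_rate`, `consistent`.
#' @export
thermodynamic_audit <- function(model, state) {
  y <- pmax(state[SPECIES_ALL], 0)
  k <- model$kinetics
  v <- model_fluxes(model, state)
  terms <- list(
    HK    = c("G6P*ADP", "GLC*ATP"),
    PGI   = c("F6P", "G6P"),
    PFK   = c("FBP*ADP", "F6P*ATP"),
    PFK2  = c("F26BP*ADP", "F6P*ATP"),
    ALD   = c("DHAP*GAP", "FBP"),
    TPI   = c("GAP", "DHAP"),
    GAPDH = c("BPG*NADH", "GAP*NAD*Pi"),
    PGK   = c("PG3*ATP", "BPG*ADP"),
    PGM   = c("PG2", "PG3"),
    ENO   = c("PEP", "PG2"),
    PK    = c("PYR*ATP", "PEP*ADP"),
    LDH   = c("LAC*NAD", "PYR*NADH"),
    CK    = c("Cr*ATP", "PCr*ADP"),
    PHGDH = c("SER*NADH", "PG3*NAD")
  )
  ev <- function(expr) eval(parse(text = expr), envir = as.list(y))
  purrr::map_dfr(names(terms), function(nm) {
    num <- ev(terms[[nm]][1]); den <- ev(terms[[nm]][2])
    gamma <- if (den > 0) num / den else Inf
    Keq <- k[[nm]]$Keq
    drive <- 1 - gamma / Keq
    rate <- v[[nm]]
    tol <- 1e-9 * max(1, abs(rate))
    tibble::tibble(
      reaction = nm, gamma = gamma, Keq = Keq, net_rate = rate,
      consistent = (abs(rate) <= tol) || (sign(rate) == sign(drive))
    )
  })
}
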