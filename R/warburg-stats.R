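# Warburg-Effect statistics over the accepted ensemble.

#' Warburg Effect ratio
#'
#' `W = J_Lac / J_Ox`: flux through LDH over flux entering the mitochondria.
#' Also returns the lactate fraction `W / (1 + W)`, the proportion of
#' pyruvate-derived flux routed to lactate (monotone in `W`; `W = 1` is the
#' boundary between primarily oxidative and primarily fermentative states).
#'
#' @param J_Lac Net lactate-producing flux (mM/hr).
#' @param J_Ox Mitochondrial pyruvate oxidation flux (mM/hr, must be > 0).
#' @return One-row tibble: `W`, `lactate_fraction`.
#' @examples
#' warburg_effect(19, 1)   # W = 19, 95% to lactate
#' @export
warburg_effect <- function(J_Lac, J_Ox) {
  if (any(J_Ox <= 0)) {
    stop("`J_Ox` must be positive: the Warburg ratio is undefined for a ",
         "non-oxidizing realization (it should have been rejected)",
         call. = FALSE)
  }
  W <- J_Lac / J_Ox
  tibble::tibble(W = W, lactate_fraction = W / (1 + W))
}

# Variable groups for the correlation panels.
we_variable_group <- function(ensemble, group) {
  switch(group,
    metabolites = paste0("conc_", c("GLC", "G6P", "F6P", "FBP", "DHAP",
                                    "GAP", "BPG", "PG3", "PG2", "PEP",
                                    "PYR", "LAC")),
    enzyme_vmax = intersect(paste0("vmax_", GLYCOLYTIC_ENZYMES),
                            names(ensemble)),
    parameters = grep("^vmax_", names(ensemble), value = TRUE),
    ratios = c("ATP_ADP", "NADH_NAD", "conc_ATP", "conc_NADH", "conc_O2",
               "conc_PCr"),
    stop("unknown variable group: ", group, call. = FALSE)
  )
}

#' Correlate the Warburg Effect with ensemble variables
#'
#' Pearson (default) correlation of each variable in the chosen group with
#' `W` across accepted realizations, in deterministic (declaration) order.
#' Constant variables yield `NA`.
#'
#' @param ensemble A `glyco_ensemble` tibble.
#' @param variable_group One of `"metabolites"` (glycolytic intermediate
#'   concentrations), `"enzyme_vmax"` (glycolytic enzyme capacities),
#'   `"parameters"` (all sampled capacities), `"ratios"` (coupled
#'   energy/redox variables).
#' @param method Correlation method (default `"pearson"` as in the
#'   ensemble-panel analyses).
#' @return Tibble: `variable`, `correlation`.
#' @export
correlate_we <- function(ensemble,
                         variable_group = c("metabolites", "enzyme_vmax",
                                            "parameters", "ratios"),
                         method = "pearson") {
  variable_group <- match.arg(variable_group)
  acc <- accepted_realizations(ensemble)
  if (nrow(acc) < 3) {
    stop("need at least 3 accepted realizations", call. = FALSE)
  }
  vars <- we_variable_group(ensemble, variable_group)
  cors <- vapply(vars, function(v) {
    x <- acc[[v]]
    if (stats::sd(x, na.rm = TRUE) == 0) return(NA_real_)
    suppressWarnings(stats::cor(x, acc$W, method = method,
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  tibble::tibble(variable = vars, correlation = unname(cors))
}

#' Split FBP levels into low and high states
#'
#' The simulated FBP distribution is bimodal: a low state in the high
#' micromolar range and a high state orders of magnitude up, in the
#' millimolar range. `fixed_threshold` labels by comparison with a cutoff
#' (default 1 mM, between the two ranges); `two_component_split` performs a
#' deterministic two-cluster 1-D split on log-concentration (initialized at
#' the extremes) and labels clusters by their means. If all values coincide
#' the two-component method falls back to the threshold with a warning.
#'
#' @param fbp_values Numeric vector of FBP concentrations (mM, > 0).
#' @param method `"fixed_threshold"` or `"two_component_split"`.
#' @param threshold Cutoff for the fixed method (mM).
#' @return Factor of labels `low`/`high`, with attribute `threshold` (the
#'   effective boundary in mM).
#' @export
fbp_state_split <- function(fbp_values,
                            method = c("fixed_threshold",
                                       "two_component_split"),
                            threshold = 1) {
  method <- match.arg(method)
  stopifnot(length(fbp_values) > 0, all(fbp_values > 0))
  if (method == "two_component_split") {
    lx <- log(fbp_values)
    if (diff(range(lx)) == 0) {
      warning("all FBP values identical; falling back to fixed threshold",
              call. = FALSE)
      method <- "fixed_threshold"
    } else {
      km <- stats::kmeans(lx, centers = range(lx))
      hi_cluster <- which.max(km$centers)
      labels <- factor(ifelse(km$cluster == hi_cluster, "high", "low"),
                       levels = c("low", "high"))
      threshold <- exp(mean(km$centers))
      return(structure(labels, threshold = threshold))
    }
  }
  structure(factor(ifelse(fbp_values > threshold, "high", "low"),
                   levels = c("low", "high")),
            threshold = threshold)
}

#' State-conditioned Spearman correlations of lactate flux
#'
#' Within each FBP state separately, Spearman correlation of `J_Lac` with
#' each glycolytic intermediate concentration. Invariant to row order.
#'
#' @param ensemble A `glyco_ensemble` tibble (accepted rows are used).
#' @param labels Factor of state labels aligned with the accepted rows of
#'   `ensemble` (e.g. from [fbp_state_split()] on `conc_FBP`); if `NULL`,
#'   computed from `conc_FBP` with the default threshold split.
#' @param metabolites Concentration columns to correlate (default the
#'   glycolytic intermediates).
#' @return Tibble: `state`, `variable`, `correlation`, `n`.
#' @export
state_conditioned_correlations <- function(ensemble, labels = NULL,
                                           metabolites = NULL) {
  acc <- accepted_realizations(ensemble)
  if (is.null(labels)) labels <- fbp_state_split(acc$conc_FBP)
  stopifnot(length(labels) == nrow(acc))
  if (is.null(metabolites)) {
    metabolites <- we_variable_group(ensemble, "metabolites")
  }
  purrr::map_dfr(levels(labels), function(st) {
    sub <- acc[labels == st, , drop = FALSE]
    if (nrow(sub) < 3) {
      return(tibble::tibble(state = st, variable = metabolites,
                            correlation = NA_real_, n = nrow(sub)))
    }
    cors <- vapply(metabolites, function(v) {
      if (stats::sd(sub[[v]]) == 0) return(NA_real_)
      suppressWarnings(stats::cor(sub$J_Lac, sub[[v]], method = "spearman"))
    }, numeric(1))
    tibble::tibble(state = st, variable = metabolites,
                   correlation = unname(cors), n = nrow(sub))
  })
}

#' Histogram-based density summary
#'
#' Deterministic probability-density estimate over equal-width bins, with the
#' mode (midpoint of the highest-density bin, lowest bin on ties), quantiles,
#' and a two-cluster bimodality flag: the values are split into two groups by
#' a deterministic 1-D 2-means on the (optionally log) axis and the
#' distribution is flagged bimodal when both groups are well populated and
#' the density dips between the group peaks.
#'
#' @param values Numeric vector.
#' @param n_bins Number of histogram bins (default 30).
#' @param log_axis Bin on the log10 axis (default `FALSE`); mode and
#'   quantiles are still reported on the original scale.
#' @param probs Quantiles to report.
#' @return List of class `glyco_density`: `density` (tibble `mid`, `density`,
#'   `count`), `mode`, `quantiles`, `bimodal`, `n`.
#' @export
density_summary <- function(values, n_bins = 30, log_axis = FALSE,
                            probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(length(values) > 0, n_bins >= 1)
  x <- if (log_axis) log10(values) else values
  rng <- range(x)
  if (diff(rng) == 0) {
    mode_val <- values[1]
    return(structure(list(
      density = tibble::tibble(mid = mode_val, density = Inf,
                               count = length(values)),
      mode = mode_val,
      quantiles = stats::quantile(values, probs),
      bimodal = FALSE, n = length(values)
    ), class = "glyco_density"))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  width <- diff(breaks)[1]
  dens <- counts / (length(x) * width)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  mode_x <- mids[which.max(dens)]

  km <- stats::kmeans(x, centers = rng)
  lo_cl <- which.min(km$centers); hi_cl <- which.max(km$centers)
  share <- min(mean(km$cluster == lo_cl), mean(km$cluster == hi_cl))
  bimodal <- FALSE
  if (share >= 0.05 && lo_cl != hi_cl) {
    c_lo <- km$centers[lo_cl]; c_hi <- km$centers[hi_cl]
    peak_lo <- max(dens[mids <= c_lo], 0)
    peak_hi <- max(dens[mids >= c_hi], 0)
    valley <- min(dens[mids > c_lo & mids < c_hi], Inf)
    bimodal <- is.finite(valley) && peak_lo > 0 && peak_hi > 0 &&
      valley < 0.75 * min(peak_lo, peak_hi)
  }
  structure(list(
    density = tibble::tibble(
      mid = if (log_axis) 10^mids else mids,
      density = dens, count = counts
    ),
    mode = if (log_axis) 10^mode_x else mode_x,
    quantiles = stats::quantile(values, probs),
    bimodal = bimodal, n = length(values)
  ), class = "glyco_density")
}

#' @export
print.glyco_density <- function(x, ...) {
  cat("<glyco_density> n =", x$n, " mode =", signif(x$mode, 4),
      if (x$bimodal) "(bimodal)" else "", "\n")
  invisible(x)
}
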