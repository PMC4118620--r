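# Experimental-side computations: 13C-lactate slope fluxes, occupancy-based
# inhibition fractions, empirical flux control coefficients from dose panels,
# and the media glucose budget arithmetic.

#' Fit a lactate flux from a labeled time course
#'
#' Ordinary least-squares line through (time, labeled lactate). The slope is
#' the glucose-to-lactate flux estimate; the time course is called linear
#' when R-squared exceeds the QC threshold (0.98).
#'
#' @param timecourse Data frame with columns `time_min` and `lactate_conc`
#'   (at least 3 points; the assay design samples 30/60/90/120 min).
#' @param r2_threshold Linearity QC threshold (default 0.98).
#' @return Object of class `glyco_flux_fit`: the underlying `lm` plus slope,
#'   standard error, R-squared and the linearity flag. Use [tidy()] /
#'   [glance()] for tabular views.
#' @export
fit_lactate_flux <- function(timecourse, r2_threshold = 0.98) {
  stopifnot(all(c("time_min", "lactate_conc") %in% names(timecourse)))
  tc <- dplyr::arrange(tibble::as_tibble(timecourse), .data$time_min)
  if (nrow(tc) < 3) {
    stop("need at least 3 time points to fit a flux", call. = FALSE)
  }
  if (any(diff(tc$time_min) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(lactate_conc ~ time_min, data = tc)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no linear signal
  structure(
    list(
      fit = fit,
      slope = unname(stats::coef(fit)[["time_min"]]),
      std_error = unname(sm$coefficients["time_min", "Std. Error"]),
      r_squared = r2,
      linear_flag = r2 > r2_threshold,
      r2_threshold = r2_threshold,
      n = nrow(tc)
    ),
    class = "glyco_flux_fit"
  )
}

#' @export
print.glyco_flux_fit <- function(x, ...) {
  cat(sprintf(
    "<glyco_flux_fit> slope = %.4g +/- %.2g per min, R^2 = %.4f (%s)\n",
    x$slope, x$std_error, x$r_squared,
    if (x$linear_flag) "linear" else "fails linearity QC"))
  invisible(x)
}

#' @rdname fit_lactate_flux
#' @param x A `glyco_flux_fit`.
#' @param ... Unused.
#' @export
tidy.glyco_flux_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(stats::coef(x$fit)),
    std_error = unname(suppressWarnings(
      summary(x$fit))$coefficients[, "Std. Error"])
  )
}

#' @rdname fit_lactate_flux
#' @export
glance.glyco_flux_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, std_error = x$std_error, r_squared = x$r_squared,
    linear_flag = x$linear_flag, n = x$n
  )
}

#' Fraction of enzyme inhibited at a dose
#'
#' Single-site reversible occupancy: `dose / (dose + Ki)`. Zero at dose 0,
#' strictly increasing, approaching 1 at saturating dose.
#'
#' @param dose Inhibitor concentration (same units as `Ki`, >= 0).
#' @param Ki Inhibition constant (> 0).
#' @return Fraction in `[0, 1)`.
#' @examples
#' fraction_inhibited(c(0, 1, 3), Ki = 1)   # 0, 0.5, 0.75
#' @export
fraction_inhibited <- function(dose, Ki) {
  if (any(!is.finite(Ki)) || any(Ki <= 0)) {
    stop("`Ki` must be positive and finite", call. = FALSE)
  }
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  dose / (dose + Ki)
}

#' Empirical flux control coefficient from a dose panel
#'
#' Least-squares slope of `ln(flux)` against `ln(1 - fraction_inhibited)`
#' (i.e. log residual activity), restricted by default to the
#' small-perturbation window of residual activity >= 0.5 where the local FCC
#' definition applies. A positive value means inhibiting the step decreases
#' lactate flux (positive control); a negative value means inhibition
#' increases it (negative control). If fewer than 3 points fall inside the
#' window, the full panel is used with a warning.
#'
#' @param panel Data frame with columns `fraction_inhibited` and `flux`
#'   (slope estimates from [fit_lactate_flux()]); one row per dose, the
#'   vehicle (fraction 0) included.
#' @param min_residual_activity Lower bound of the fitting window
#'   (default 0.5).
#' @return One-row tibble: `fcc`, `std_error`, `n_used`, `window_respected`.
#' @export
empirical_fcc <- function(panel, min_residual_activity = 0.5) {
  stopifnot(all(c("fraction_inhibited", "flux") %in% names(panel)))
  df <- tibble::as_tibble(panel) |>
    dplyr::filter(is.finite(.data$flux), .data$flux > 0,
                  .data$fraction_inhibited >= 0,
                  .data$fraction_inhibited < 1) |>
    dplyr::mutate(residual = 1 - .data$fraction_inhibited)
  window <- dplyr::filter(df, .data$residual >= min_residual_activity)
  window_respected <- nrow(window) >= 3
  if (!window_respected) {
    warning("fewer than 3 points in the small-perturbation window; ",
            "fitting the full dose range", call. = FALSE)
    window <- df
  }
  if (nrow(window) < 3) {
    stop("need at least 3 valid (dose, flux) pairs", call. = FALSE)
  }
  fit <- stats::lm(log(flux) ~ log(residual), data = window)
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(
    fcc = unname(stats::coef(fit)[["log(residual)"]]),
    std_error = unname(sm["log(residual)", "Std. Error"]),
    n_used = nrow(window),
    window_respected = window_respected
  )
}

#' Media glucose budget
#'
#' Back-of-envelope check that media glucose is in excess of cellular
#' consumption over an imaging experiment: consumed = uptake rate x cells x
#' duration; available = media concentration x volume.
#'
#' @param uptake_rate Per-cell glucose uptake (fmol/cell/hr).
#' @param n_cells Number of cells.
#' @param duration Duration (hr).
#' @param media_volume Media volume (microliters).
#' @param glucose_conc Media glucose concentration (micromolar).
#' @return One-row tibble: `consumed_nmol` (rounded to nearest nmol),
#'   `consumed_nmol_exact`, `available_nmol`, `excess_flag`.
#' @examples
#' media_glucose_budget(100, 2000, 24, 400, 750)
#' @export
media_glucose_budget <- function(uptake_rate, n_cells, duration,
                                 media_volume, glucose_conc) {
  stopifnot(uptake_rate >= 0, n_cells >= 0, duration >= 0,
            media_volume >= 0, glucose_conc >= 0)
  # fmol -> nmol: 1e-6; uM * uL = pmol -> nmol: 1e-3
  consumed <- uptake_rate * n_cells * duration * 1e-6
  available <- glucose_conc * media_volume * 1e-3
  tibble::tibble(
    consumed_nmol = round(consumed),
    consumed_nmol_exact = consumed,
    available_nmol = available,
    excess_flag = available > consumed
  )
}

#' Fit fluxes for every condition/replicate of a tracer table
#'
#' Applies [fit_lactate_flux()] per (condition, replicate) group of a tidy
#' tracer table.
#'
#' @param timecourses Data frame with columns `condition`, `replicate`,
#'   `time_min`, `lactate_conc`.
#' @return Tibble: one row per condition x replicate with `slope`,
#'   `std_error`, `r_squared`, `linear_flag`.
#' @export
fit_tracer_table <- function(timecourses) {
  timecourses |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::group_modify(~ glance(fit_lactate_flux(.x))) |>
    dplyr::ungroup()
}
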