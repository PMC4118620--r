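# Steady-state solution of one model realization.
#
# Strategy: integrate the stiff ODE system (deSolve::lsoda) in geometrically
# growing time chunks, testing a relative-derivative criterion after each
# chunk; once the trajectory has plateaued, polish the root with a damped
# Newton iteration on the conservation-reduced system so fluxes are resolved
# far below the finite-difference scale used by the control analysis.

# Species eliminated through the three conservation laws.
REDUCED_DROP <- c("ADP", "NAD", "Cr")

reduced_names <- function(media_dynamic) {
  keep <- setdiff(SPECIES_INTRACELLULAR, REDUCED_DROP)
  if (media_dynamic) c(keep, SPECIES_MEDIA) else keep
}

expand_state <- function(x, pools, media, media_dynamic) {
  full <- c(x, if (!media_dynamic) media)
  full[["ADP"]] <- max(pools[["adenylate"]] - full[["ATP"]] - full[["AMP"]], 0)
  full[["NAD"]] <- max(pools[["nad"]] - full[["NADH"]], 0)
  full[["Cr"]] <- max(pools[["creatine"]] - full[["PCr"]], 0)
  full[SPECIES_ALL]
}

reduced_rhs <- function(model) {
  media_dynamic <- isTRUE(model$params$media_dynamic)
  keep <- reduced_names(media_dynamic)
  pools <- model$params$pools
  media <- model$params$media
  function(x) {
    full <- expand_state(x, pools, media, media_dynamic)
    model_odes(model, full)[keep]
  }
}

num_jacobian <- function(f, x, h_rel = 1e-6, h_abs = 1e-9) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(h_rel * abs(x[j]), h_abs)
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- max(x[j] - h, 0)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

# max_i |dC_i/dt| / max(C_i, floor), the convergence measure (1/hr).
steady_residual <- function(model, state, floor = 1e-9) {
  d <- model_odes(model, state)
  dyn <- if (isTRUE(model$params$media_dynamic)) SPECIES_ALL
         else SPECIES_INTRACELLULAR
  max(abs(d[dyn]) / pmax(state[dyn], floor))
}

#' Solve the model to steady state
#'
#' Integrates the stiff ODE system from `init` until the relative derivative
#' criterion `max |dC/dt| / max(C, floor) <= tol` is met (or the time horizon
#' is exhausted), then polishes the root by damped Newton iteration on the
#' conservation-reduced system. The convergence flag is honest: solver
#' failures and non-plateauing trajectories return `converged = FALSE`
#' rather than raising.
#'
#' @param model A `glyco_model`.
#' @param init Named initial state (default: the parameter set's baseline).
#' @param tol Relative-derivative tolerance (default 1e-6 per hr).
#' @param floor Concentration floor for the relative criterion (mM).
#' @param t_max Time horizon in model hours (default 1e4).
#' @param warm_start Logical; if `TRUE`, `init` is assumed to be near the
#'   root and Newton polishing is attempted before any integration (the
#'   integrator is still the fallback).
#' @param newton_only Logical; if `TRUE`, only the warm Newton path is used
#'   (no integration fallback). This is branch continuation: the solution
#'   smoothly connected to `init` is returned, or a non-converged result if
#'   Newton fails. Used by the control analysis so a perturbed re-solve can
#'   never jump to a different stable branch of a bistable realization.
#' @return List with `state` (named vector, mM), `fluxes` (named vector,
#'   mM/hr), `converged` (logical), `residual` (1/hr), and `jacobian` (the
#'   reduced-system Jacobian at the returned state).
#' @export
solve_steady_state <- function(model, init = initial_state(model$params),
                               tol = 1e-6, floor = 1e-9, t_max = 1e4,
                               warm_start = FALSE, newton_only = FALSE) {
  media_dynamic <- isTRUE(model$params$media_dynamic)
  keep <- reduced_names(media_dynamic)
  f <- reduced_rhs(model)
  state <- init[SPECIES_ALL]

  polish <- function(x0) {
    x <- x0
    for (it in 1:25) {
      fx <- f(x)
      nfx <- max(abs(fx))
      # converge in the same relative sense as the steady-state criterion
      if (max(abs(fx) / pmax(x, floor)) < tol / 10) break
      J <- num_jacobian(f, x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- pmax(x + lam * step, 0)
        fn <- f(xn)
        if (all(is.finite(fn)) && max(abs(fn)) < nfx * 0.9 + 1e-14) {
          x <- xn
          break
        }
        lam <- lam / 2
        if (lam < 1e-4) return(NULL)
      }
    }
    x
  }

  finish <- function(state) {
    res <- steady_residual(model, state, floor)
    J <- num_jacobian(f, state[keep])
    list(state = state, fluxes = model_fluxes(model, state),
         converged = res <= tol, residual = res, jacobian = J)
  }

  if (warm_start || newton_only) {
    x <- polish(state[keep])
    if (!is.null(x)) {
      cand <- expand_state(x, model$params$pools, model$params$media,
                           media_dynamic)
      res <- steady_residual(model, cand, floor)
      if (res <= tol) return(finish(cand))
    }
    if (newton_only) {
      # bounded local fallback: a few hours of integration from the warm
      # state (which stays within the current basin), then polish again
      rhs_local <- make_rhs(model)
      st <- state
      t0 <- 0
      for (t1 in c(2, 10, 50, 250)) {
        out <- suppressWarnings(tryCatch(
          deSolve::lsoda(y = st, times = c(t0, t1), func = rhs_local,
                         parms = NULL, rtol = 1e-6, atol = 1e-8,
                         maxsteps = 10000),
          error = function(e) NULL
        ))
        if (is.null(out) || nrow(out) < 2 || any(!is.finite(out[2, -1]))) {
          break
        }
        st <- pmax(out[2, -1], 0)
        names(st) <- SPECIES_ALL
        t0 <- t1
        x <- polish(st[keep])
        if (!is.null(x)) {
          cand <- expand_state(x, model$params$pools, model$params$media,
                               media_dynamic)
          if (steady_residual(model, cand, floor) <= tol &&
              all(cand >= 0)) {
            return(finish(cand))
          }
        }
      }
      return(list(state = state, fluxes = model_fluxes(model, state),
                  converged = FALSE,
                  residual = steady_residual(model, state, floor),
                  jacobian = NULL))
    }
  }

  # Classify a Newton-polished root: a stable root (or one the trajectory has
  # already plateaued onto) is the answer; an unstable root with the
  # trajectory still moving means the attractor is not a fixed point (e.g. a
  # glycolytic oscillation), so further integration is pointless.
  try_polish <- function(state, res) {
    x <- polish(state[keep])
    if (is.null(x)) return(list(verdict = "none"))
    cand <- expand_state(x, model$params$pools, model$params$media,
                         media_dynamic)
    if (any(cand < 0) || steady_residual(model, cand, floor) > tol) {
      return(list(verdict = "none"))
    }
    if (res <= 1e-3) return(list(verdict = "root", state = cand))
    J <- num_jacobian(f, cand[keep])
    ev <- eigen(J, only.values = TRUE)$values
    if (max(Re(ev)) <= 1e-6) {
      list(verdict = "root", state = cand)
    } else {
      list(verdict = "unstable_root", state = cand)
    }
  }

  fail <- function(state) {
    list(state = state, fluxes = model_fluxes(model, state),
         converged = FALSE,
         residual = steady_residual(model, state, floor), jacobian = NULL)
  }

  rhs <- make_rhs(model)
  t0 <- 0
  res_prev <- Inf
  for (t1 in unique(c(1, 10, 100, 300, 1e3, 3e3, pmin(1e4, t_max), t_max))) {
    out <- suppressWarnings(tryCatch(
      deSolve::lsoda(y = state, times = c(t0, t1), func = rhs, parms = NULL,
                     rtol = 1e-6, atol = 1e-8, maxsteps = 20000),
      error = function(e) NULL
    ))
    if (is.null(out) || nrow(out) < 2 || any(!is.finite(out[2, -1]))) {
      return(fail(state))
    }
    state <- pmax(out[2, -1], 0)
    names(state) <- SPECIES_ALL
    t0 <- t1
    res <- steady_residual(model, state, floor)
    if (res <= tol) return(finish(state))
    if (res <= 100) {
      p <- try_polish(state, res)
      if (p$verdict == "root") return(finish(p$state))
      # orbiting an unstable fixed point: no steady state will be reached
      if (p$verdict == "unstable_root" && t1 >= 100) return(fail(state))
    }
    # stalled far from any root (e.g. orbiting a limit cycle): give up early;
    # slowly relaxing trajectories with already-small residuals keep going
    if (t1 >= 1e3 && res > 1e-2 && res > res_prev * 0.85) return(fail(state))
    res_prev <- res
  }
  finish(state)
}

#' Integrate a trajectory of the model
#'
#' Thin wrapper around [deSolve::lsoda()] returning a tidy tibble, used for
#' conservation checks and tracer-style dynamic simulations.
#'
#' @param model A `glyco_model`.
#' @param times Numeric vector of output times (hours).
#' @param init Named initial state.
#' @return Tibble with a `time` column and one column per species (mM).
#' @export
integrate_model <- function(model, times, init = initial_state(model$params)) {
  out <- deSolve::lsoda(y = init[SPECIES_ALL], times = times,
                        func = make_rhs(model), parms = NULL,
                        rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
  tibble::as_tibble(as.data.frame(out))
}
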