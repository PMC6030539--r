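#' Calibrate the adult transmission coefficient for frequency-dependent mode
#'
#' Frequency-dependent analyses are compared against density-dependent ones
#' by calibrating `beta_A` so that the initial (`beta_J = beta_A`) age and
#' disease structure match the density-dependent case. Because
#' \eqn{\lambda^{FD} = \beta I / N}, the calibrated coefficient is
#' `beta_A_DD * N*`, where `N*` is the total density of the density-dependent
#' initial endemic equilibrium; the matched state is then an equilibrium of
#' the frequency-dependent system exactly.
#'
#' @param params_dd A density-dependent [model_params()] object.
#' @return The calibrated `beta_A` (per time) for frequency-dependent mode.
#'   Errors if the density-dependent initial equilibrium is disease-free or
#'   the host is not viable (nothing to match).
#' @seealso [calibrated_fd_params()] for the full parameter object.
#' @export
calibrate_fd_beta <- function(params_dd) {
  stopifnot(inherits(params_dd, "jsev_params"))
  if (params_dd$transmission_mode != "density_dependent")
    stop("calibration starts from a density-dependent parameterization")
  eq <- .resident_equilibrium(params_dd$beta_A, params_dd)
  if (eq$extinct)
    stop("calibration infeasible: host not viable under density-dependent transmission")
  if (eq$state[3] + eq$state[4] < 1e-8)
    stop("calibration infeasible: density-dependent initial equilibrium is disease-free")
  params_dd$beta_A * sum(eq$state)
}

#' Frequency-dependent parameter set calibrated to a density-dependent one
#'
#' @param params_dd A density-dependent [model_params()] object with an
#'   endemic initial equilibrium.
#' @return A [model_params()] object in frequency-dependent mode whose
#'   initial equilibrium matches the density-dependent one.
#' @export
calibrated_fd_params <- function(params_dd) {
  bfd <- calibrate_fd_beta(params_dd)
  update_params(params_dd, beta_A = bfd,
                transmission_mode = "frequency_dependent")
}

#' Evolutionary endpoint reached from a starting trait
#'
#' Follows the selection gradient from `beta_init` in small trait steps,
#' recomputing the attracting resident equilibrium at every step (with
#' stability verified, so that loss of the endemic attractor is detected
#' rather than continued onto an unstable branch). Stops at the first
#' convergence-stable interior singular strategy, at a trait boundary, or --
#' under frequency-dependent transmission only -- when evolution drives the
#' host extinct (evolutionary suicide).
#'
#' @param params A [model_params()] object.
#' @param beta_init Starting trait (default `beta_A`, the unevolved state).
#' @param step_n Number of trait steps spanning the interval (default 150).
#' @return List with `beta_star` (trait value or `NA` when the host went
#'   extinct), `viable` (logical), `attractor` (`"interior"`, `"boundary_min"`,
#'   `"boundary_max"`, `"extinct"`, or `"initial_extinct"`), and
#'   `final_state` (the resident equilibrium at the endpoint, or `NULL`).
#' @export
evolve_to_endpoint <- function(params, beta_init = params$beta_A,
                               step_n = 150) {
  stopifnot(inherits(params, "jsev_params"))
  lo <- params$beta_A; hi <- params$d * params$beta_A
  if (beta_init < lo - 1e-12 || beta_init > hi + 1e-12)
    stop("beta_init outside the admissible trait interval")
  if (hi <= lo) {
    eq <- .resident_equilibrium(lo, params)
    return(list(beta_star = lo, viable = !eq$extinct,
                attractor = "boundary_min",
                final_state = if (eq$extinct) NULL else eq$state))
  }
  eq <- .resident_equilibrium(beta_init, params)
  if (eq$extinct)
    return(list(beta_star = NA_real_, viable = FALSE,
                attractor = "initial_extinct", final_state = NULL))
  step <- (hi - lo) / step_n
  cur <- beta_init
  env <- .environment_of(eq$state, params)
  g_cur <- .gradient_analytic(cur, env, params)
  dir <- sign(g_cur)
  if (dir == 0)
    return(list(beta_star = cur, viable = TRUE, attractor = "interior",
                final_state = eq$state))
  state <- eq$state
  repeat {
    nxt <- cur + dir * step
    if (nxt <= lo + 1e-15) {
      eqb <- .resident_equilibrium(lo, params, guess = state)
      if (eqb$extinct)
        return(list(beta_star = NA_real_, viable = FALSE,
                    attractor = "extinct", final_state = NULL))
      return(list(beta_star = lo, viable = TRUE, attractor = "boundary_min",
                  final_state = eqb$state))
    }
    if (nxt >= hi - 1e-15) {
      eqb <- .resident_equilibrium(hi, params, guess = state)
      if (eqb$extinct)
        return(list(beta_star = NA_real_, viable = FALSE,
                    attractor = "extinct", final_state = NULL))
      return(list(beta_star = hi, viable = TRUE, attractor = "boundary_max",
                  final_state = eqb$state))
    }
    eq2 <- .resident_equilibrium(nxt, params, guess = state)
    if (eq2$extinct)
      return(list(beta_star = NA_real_, viable = FALSE,
                  attractor = "extinct", final_state = NULL))
    env2 <- .environment_of(eq2$state, params)
    g_nxt <- .gradient_analytic(nxt, env2, params)
    if (sign(g_nxt) != dir && sign(g_nxt) != 0) {
      # sign change: refine the convergence-stable root by bisection
      gfun <- function(b) {
        e <- .resident_equilibrium(b, params, guess = eq2$state)
        if (e$extinct) return(NA_real_)
        .gradient_analytic(b, .environment_of(e$state, params), params)
      }
      root <- tryCatch(
        stats::uniroot(gfun, sort(c(cur, nxt)), tol = 1e-8 * (hi - lo))$root,
        error = function(e) (cur + nxt) / 2)
      eqr <- .resident_equilibrium(root, params, guess = eq2$state)
      if (eqr$extinct)
        return(list(beta_star = NA_real_, viable = FALSE,
                    attractor = "extinct", final_state = NULL))
      return(list(beta_star = root, viable = TRUE, attractor = "interior",
                  final_state = eqr$state))
    }
    cur <- nxt; state <- eq2$state
  }
}

#' Lifespan or maturation-probability sweep
#'
#' Reproduces the sweep experiment design: for every value of the axis
#' quantity (host lifespan `1/b` at fixed `g0`, or baseline maturation
#' probability `g0/(b + g0)` at fixed `b`) the initial (`beta_J = beta_A`)
#' equilibrium is computed, the trait is evolved from the unevolved state,
#' and the evolved equilibrium is summarised. Under frequency-dependent
#' transmission `beta_A` is first calibrated per point against the
#' corresponding density-dependent initial equilibrium; points where the
#' density-dependent equilibrium is disease-free are flagged
#' (`calibration_ok = FALSE`) and not evolved.
#'
#' @param axis `"lifespan"` or `"maturation_probability"`.
#' @param axis_values Positive grid of the axis quantity (lifespans, or
#'   probabilities in (0, 1)).
#' @param base_params Base [model_params()] object. For a frequency-dependent
#'   sweep pass a *density-dependent* parameterization with
#'   `mode = "frequency_dependent"`: its `beta_A` is the density-dependent
#'   reference used for calibration.
#' @param mode `"density_dependent"` (default: taken from `base_params`) or
#'   `"frequency_dependent"`.
#' @param step_n Trait resolution of [evolve_to_endpoint()].
#' @return An object of class `jsev_sweep`: list with `axis`, `records` (one
#'   data-frame row per axis value) and `params`.
#' @export
sweep_experiment <- function(axis = c("lifespan", "maturation_probability"),
                             axis_values, base_params,
                             mode = base_params$transmission_mode,
                             step_n = 150) {
  axis <- match.arg(axis)
  stopifnot(inherits(base_params, "jsev_params"), all(axis_values > 0))
  if (axis == "maturation_probability" && any(axis_values >= 1))
    stop("maturation probabilities must lie in (0, 1)")
  fd <- identical(mode, "frequency_dependent")
  rows <- vector("list", length(axis_values))
  for (i in seq_along(axis_values)) {
    v <- axis_values[i]
    p_dd <- if (axis == "lifespan")
      update_params(base_params, b = 1 / v,
                    transmission_mode = "density_dependent")
    else
      update_params(base_params, g0 = base_params$b * v / (1 - v),
                    transmission_mode = "density_dependent")
    rec <- .sweep_point(p_dd, fd, step_n)
    rec$axis_value <- v
    rec$b <- p_dd$b; rec$g0 <- p_dd$g0
    rows[[i]] <- as.data.frame(rec)
  }
  records <- do.call(rbind, rows)
  records <- records[, c("axis_value", "b", "g0", "beta_A_used",
                         "calibration_ok", "initial_viable",
                         "initial_prevalence", "initial_juvenile_fraction",
                         "evolved_viable", "evolved_beta_ratio",
                         "evolved_prevalence", "evolved_juvenile_fraction")]
  structure(list(axis = axis, records = records, params = base_params,
                 mode = if (fd) "frequency_dependent" else "density_dependent"),
            class = "jsev_sweep")
}

# One sweep point: initial equilibrium, (optional FD calibration), evolution
# from the unevolved state, evolved summaries.
.sweep_point <- function(p_dd, fd, step_n) {
  out <- list(beta_A_used = NA_real_, calibration_ok = !fd,
              initial_viable = FALSE,
              initial_prevalence = NA_real_,
              initial_juvenile_fraction = NA_real_,
              evolved_viable = FALSE, evolved_beta_ratio = NA_real_,
              evolved_prevalence = NA_real_,
              evolved_juvenile_fraction = NA_real_)
  eq_dd <- .resident_equilibrium(p_dd$beta_A, p_dd)
  if (eq_dd$extinct) return(out)          # demographically nonviable
  endemic <- eq_dd$state[3] + eq_dd$state[4] >= 1e-8
  if (!fd) {
    p <- p_dd
    out$beta_A_used <- p$beta_A
    init_state <- eq_dd$state
  } else {
    if (!endemic) {                        # nothing to match: flagged point
      out$initial_viable <- TRUE
      s <- summarize_structure(eq_dd$state)
      out$initial_prevalence <- s[["prevalence"]]
      out$initial_juvenile_fraction <- s[["juvenile_fraction"]]
      return(out)
    }
    bfd <- p_dd$beta_A * sum(eq_dd$state)
    p <- update_params(p_dd, beta_A = bfd,
                       transmission_mode = "frequency_dependent")
    out$beta_A_used <- bfd
    out$calibration_ok <- TRUE
    # initial viability under FD judged from the standard initial condition
    eq_fd <- .resident_equilibrium(p$beta_A, p)
    if (eq_fd$extinct) return(out)
    init_state <- eq_fd$state
  }
  out$initial_viable <- TRUE
  s <- summarize_structure(init_state)
  out$initial_prevalence <- s[["prevalence"]]
  out$initial_juvenile_fraction <- s[["juvenile_fraction"]]
  ev <- evolve_to_endpoint(p, beta_init = p$beta_A, step_n = step_n)
  if (!ev$viable) return(out)
  out$evolved_viable <- TRUE
  out$evolved_beta_ratio <- ev$beta_star / p$beta_A
  se <- summarize_structure(ev$final_state)
  out$evolved_prevalence <- se[["prevalence"]]
  out$evolved_juvenile_fraction <- se[["juvenile_fraction"]]
  out
}

#' @export
print.jsev_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d points, %s transmission, %s trade-off)\n",
              x$axis, nrow(x$records), x$mode, x$params$tradeoff_target))
  print(x$records, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.jsev_sweep <- function(x, ...) x$records

#' Evolutionary-suicide gap of a frequency-dependent sweep
#'
#' Returns the maximal contiguous runs of axis values where the host is
#' initially viable but evolution drives it extinct (the gap between the
#' initial and evolved viability thresholds). Empty, with a warning, when the
#' parameterization is density-dependent (host extinction by the pathogen is
#' impossible there).
#'
#' @param axis_values Ordered axis grid.
#' @param base_params_fd Parameterization as for [sweep_experiment()] with
#'   frequency-dependent mode.
#' @param axis Sweep axis (default `"lifespan"`).
#' @param sweep Optional precomputed `jsev_sweep` (axis values must match).
#' @param ... Passed to [sweep_experiment()].
#' @return List of numeric ranges `c(from, to)` of axis values inside the
#'   gap; empty list if none. The underlying sweep is attached as attribute
#'   `"sweep"`.
#' @export
suicide_gap <- function(axis_values, base_params_fd, axis = "lifespan",
                        sweep = NULL, ...) {
  if (base_params_fd$transmission_mode != "frequency_dependent") {
    warning("density-dependent transmission cannot drive the host extinct; empty gap")
    return(structure(list(), sweep = NULL))
  }
  if (is.null(sweep))
    sweep <- sweep_experiment(axis, axis_values, base_params_fd,
                              mode = "frequency_dependent", ...)
  r <- sweep$records
  in_gap <- r$initial_viable & r$calibration_ok & !r$evolved_viable
  runs <- list()
  i <- 1
  while (i <= length(in_gap)) {
    if (isTRUE(in_gap[i])) {
      j <- i
      while (j < length(in_gap) && isTRUE(in_gap[j + 1])) j <- j + 1
      runs[[length(runs) + 1]] <- c(r$axis_value[i], r$axis_value[j])
      i <- j + 1
    } else i <- i + 1
  }
  structure(runs, sweep = sweep)
}
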