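#' Closed-form disease-free equilibrium
#'
#' With `I_J = I_A = 0` the model reduces to a two-stage demographic model
#' whose equilibrium solves the birth-death balance: `S_A/S_J = g(beta_J)/b`
#' and \eqn{N^* = (1/q)\,(1 - b(b + g)/(a g))}. The host is viable
#' (disease-free) iff `a * g > b * (b + g)`; otherwise the all-zero state is
#' returned. Disease parameters cannot affect this state.
#'
#' @param beta_J Trait value (affects the state only through the trade-off).
#' @param params A [model_params()] object.
#' @return A [population_state()].
#' @examples
#' p <- preset_params("fig1")
#' total_density(disease_free_equilibrium(p$beta_A, p))  # 930 at fig1 values
#' @export
disease_free_equilibrium <- function(beta_J, params) {
  stopifnot(inherits(params, "jsev_params"))
  tr <- tradeoff_value(beta_J, params)
  a <- tr$a; g <- tr$g
  if (a * g <= params$b * (params$b + g))
    return(population_state(0, 0, 0, 0))
  N <- (1 - params$b * (params$b + g) / (a * g)) / params$q
  S_J <- N / (1 + g / params$b)
  population_state(S_J, N - S_J, 0, 0)
}

#' Basic reproduction number of the pathogen
#'
#' Next-generation computation on the infected subsystem linearised at the
#' disease-free equilibrium. Because maturation does not end infection and
#' infectiousness is stage-independent, the expected infectious lifetime is
#' `1/Gamma` regardless of stage, giving the closed form
#' \eqn{R_0 = (\beta_J S_J^* + \beta_A S_A^*) / \Gamma} under
#' density-dependent transmission and the same expression divided by
#' \eqn{N^*} under frequency-dependent transmission.
#'
#' @param beta_J Trait value.
#' @param params A [model_params()] object.
#' @return `R0` (dimensionless). The pathogen can invade the disease-free
#'   equilibrium iff `R0 > 1`.
#' @export
basic_reproduction_number <- function(beta_J, params) {
  dfe <- disease_free_equilibrium(beta_J, params)
  N <- total_density(dfe)
  if (N <= 0)
    stop("host not viable: R0 is undefined without a host population")
  r0 <- (beta_J * dfe[["S_J"]] + params$beta_A * dfe[["S_A"]]) / params$Gamma
  if (params$transmission_mode == "frequency_dependent") r0 <- r0 / N
  unname(r0)
}

#' Prevalence and juvenile fraction of a population state
#'
#' @param state A [population_state()] with positive total density.
#' @return Named vector: `prevalence = (I_J + I_A)/N` and
#'   `juvenile_fraction = (S_J + I_J)/N`.
#' @export
summarize_structure <- function(state) {
  y <- unclass(state)[1:4]
  N <- sum(y)
  if (N <= 0) stop("cannot summarize an empty population (N = 0)")
  c(prevalence = (y[[3]] + y[[4]]) / N,
    juvenile_fraction = (y[[1]] + y[[3]]) / N)
}

# Numerical Jacobian of the single-strain RHS at y (central differences).
.rhs_jacobian <- function(y, beta_J, params) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    h <- 1e-7 * max(1, abs(y[j]))
    e <- numeric(4); e[j] <- h
    J[, j] <- (.rhs_core(pmax(y + e, 0), beta_J, params) -
               .rhs_core(pmax(y - e, 0), beta_J, params)) / (2 * h)
  }
  J
}

# Newton polish of an equilibrium from a starting guess. Returns the polished
# state or NULL if the iteration fails or leaves the positive cone.
.newton_polish <- function(y0, beta_J, params, tol = 1e-12, maxit = 30) {
  y <- pmax(y0, 0)
  for (i in seq_len(maxit)) {
    r <- .rhs_core(y, beta_J, params)
    if (max(abs(r)) < tol) return(pmax(y, 0))
    J <- .rhs_jacobian(y, beta_J, params)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # damped update to stay near the positive cone
    lam <- 1
    repeat {
      ynew <- y + lam * step
      if (min(ynew) > -1e-8 * max(1, max(abs(y)))) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    y <- ynew
  }
  r <- .rhs_core(pmax(y, 0), beta_J, params)
  if (max(abs(r)) < 1e-8) pmax(y, 0) else NULL
}

# Is the equilibrium y locally stable (all Jacobian eigenvalue real parts
# below a small positive tolerance)?
.is_stable <- function(y, beta_J, params, tol = 1e-7) {
  ev <- eigen(.rhs_jacobian(y, beta_J, params), only.values = TRUE)$values
  max(Re(ev)) < tol
}

# Default initial condition: the disease-free equilibrium with 1% of each
# stage moved into the infected classes (the "initial" convention).
.default_init <- function(beta_J, params) {
  dfe <- disease_free_equilibrium(beta_J, params)
  y <- unclass(dfe)[1:4]
  if (sum(y) <= 0) return(y)
  c(0.99 * y[1], 0.99 * y[2], 0.01 * y[1], 0.01 * y[2])
}

# Fast attracting-equilibrium solver used throughout the adaptive-dynamics
# machinery. Strategy: (optional warm-start Newton with stability check),
# otherwise integrate from the default init until the RHS is small, then
# Newton-polish and verify stability by reintegration if needed.
# Returns list(state, extinct).
.resident_equilibrium <- function(beta_J, params, guess = NULL,
                                  t_chunk = 2000, t_max = 1e5, tol = 1e-9) {
  ext_thresh <- 1e-8
  if (!is.null(guess) && sum(guess) > ext_thresh) {
    y <- .newton_polish(guess, beta_J, params)
    if (!is.null(y) && sum(y) > ext_thresh &&
        max(abs(y - guess)) < 0.2 * max(1, max(abs(guess))) &&
        .is_stable(y, beta_J, params))
      return(list(state = y, extinct = FALSE, converged = TRUE))
  }
  y <- if (!is.null(guess) && sum(guess) > ext_thresh) pmax(guess, 0)
       else .default_init(beta_J, params)
  if (all(y <= ext_thresh))
    return(list(state = numeric(4), extinct = TRUE, converged = TRUE))
  t <- 0
  repeat {
    sol <- .integrate(y, beta_J, params, c(0, t_chunk))
    y <- pmax(as.numeric(sol[nrow(sol), 2:5]), 0)
    t <- t + t_chunk
    if (all(y < ext_thresh))
      return(list(state = numeric(4), extinct = TRUE, converged = TRUE))
    r <- .rhs_core(y, beta_J, params)
    if (max(abs(r)) < 1e-6 * max(1, max(y))) {
      p <- .newton_polish(y, beta_J, params)
      if (!is.null(p) && any(p > ext_thresh) && min(p) >= 0 &&
          .is_stable(p, beta_J, params))
        return(list(state = p, extinct = FALSE, converged = TRUE))
      if (!is.null(p) && all(p <= ext_thresh))
        return(list(state = numeric(4), extinct = TRUE, converged = TRUE))
    }
    if (t >= t_max)
      return(list(state = y, extinct = sum(y) < ext_thresh, converged = FALSE))
  }
}

#' Integrate to an attracting ecological state and classify it
#'
#' Runs stiff-capable integration from `init` with an event-based early exit
#' when the right-hand side drops below `tol`, followed by a Newton polish
#' from the integration endpoint. The reported state is classified as
#' `extinct` (total density below the extinction threshold 1e-8),
#' `disease_free` (host present, infected density below threshold) or
#' `endemic`.
#'
#' @param init A [population_state()] (defaults to the disease-free
#'   equilibrium with 1% of hosts moved to the infected classes).
#' @param beta_J Trait value.
#' @param params A [model_params()] object.
#' @param t_max Maximum integration time (default 1e5).
#' @param tol Convergence tolerance on `max |RHS|` (default 1e-9).
#' @return An object of class `jsev_equilibrium`: list with `state`,
#'   `classification`, `converged`, `prevalence`, `juvenile_fraction`,
#'   `residual`, `beta_J`.
#' @export
run_to_equilibrium <- function(init = NULL, beta_J, params,
                               t_max = 1e5, tol = 1e-9) {
  stopifnot(inherits(params, "jsev_params"), t_max > 0, tol > 0)
  ext_thresh <- 1e-8
  y <- if (is.null(init)) .default_init(beta_J, params) else unclass(init)[1:4]
  if (any(y < 0)) stop("init must be non-negative")
  converged <- FALSE
  if (sum(y) <= ext_thresh) {
    y <- numeric(4); converged <- TRUE
  } else {
    tr <- tradeoff_value(beta_J, params)
    fun <- function(t, yy, parms) list(.rhs_core(yy, beta_J, params,
                                                 a = tr$a, g = tr$g))
    rootfun <- function(t, yy, parms) {
      r <- .rhs_core(yy, beta_J, params, a = tr$a, g = tr$g)
      max(abs(r)) - tol
    }
    sol <- tryCatch(
      deSolve::lsodar(pmax(y, 0), c(0, t_max), fun, parms = NULL,
                      rootfunc = rootfun, rtol = 1e-10, atol = 1e-12),
      error = function(e) stop("integration failure: ", conditionMessage(e)))
    y <- pmax(as.numeric(sol[nrow(sol), 2:5]), 0)
    if (max(y) < 1e-4 && sum(y) > 0) {
      # the RHS also vanishes along the extinction manifold, so the early
      # exit can fire during slow decay: integrate on to resolve it
      sol2 <- .integrate(y, beta_J, params, c(0, t_max))
      y <- pmax(as.numeric(sol2[nrow(sol2), 2:5]), 0)
    }
    p <- .newton_polish(y, beta_J, params)
    if (!is.null(p)) y <- p
    converged <- max(abs(.rhs_core(y, beta_J, params))) < tol
  }
  y[y < ext_thresh] <- 0           # densities below the threshold are zero
  residual <- if (sum(y) > 0) max(abs(.rhs_core(y, beta_J, params))) else 0
  N <- sum(y)
  classification <- if (N < ext_thresh) "extinct"
                    else if (y[3] + y[4] < ext_thresh) "disease_free"
                    else "endemic"
  st <- population_state(y[1], y[2], y[3], y[4])
  summ <- if (N >= ext_thresh) summarize_structure(st)
          else c(prevalence = 0, juvenile_fraction = 0)
  structure(list(state = st, classification = classification,
                 converged = converged,
                 prevalence = unname(summ["prevalence"]),
                 juvenile_fraction = unname(summ["juvenile_fraction"]),
                 residual = residual, beta_J = beta_J),
            class = "jsev_equilibrium")
}

#' @export
print.jsev_equilibrium <- function(x, ...) {
  cat(sprintf("Ecological equilibrium (beta_J = %g): %s%s\n", x$beta_J,
              x$classification,
              if (x$converged) "" else " [NOT converged]"))
  y <- unclass(x$state)[1:4]
  cat(sprintf("  S_J = %.4g, S_A = %.4g, I_J = %.4g, I_A = %.4g (N = %.4g)\n",
              y[1], y[2], y[3], y[4], sum(y)))
  cat(sprintf("  prevalence = %.4g, juvenile fraction = %.4g, residual = %.2e\n",
              x$prevalence, x$juvenile_fraction, x$residual))
  invisible(x)
}

#' @export
as.data.frame.jsev_equilibrium <- function(x, ...) {
  y <- unclass(x$state)[1:4]
  data.frame(beta_J = x$beta_J, classification = x$classification,
             S_J = y[1], S_A = y[2], I_J = y[3], I_A = y[4],
             prevalence = x$prevalence,
             juvenile_fraction = x$juvenile_fraction,
             converged = x$converged, residual = x$residual)
}

#' Serialize an equilibrium report to JSON
#' @param x A `jsev_equilibrium`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
equilibrium_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "jsev_equilibrium"))
  obj <- list(beta_J = x$beta_J, classification = x$classification,
              state = as.list(unclass(x$state)[1:4]),
              prevalence = x$prevalence,
              juvenile_fraction = x$juvenile_fraction,
              converged = x$converged, residual = x$residual)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
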