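#' Forces of infection on juveniles and adults
#'
#' Density-dependent transmission: \eqn{\lambda_J = \beta_J (I_J + I_A)},
#' \eqn{\lambda_A = \beta_A (I_J + I_A)}. Frequency-dependent:
#' \eqn{\lambda_J = \beta_J (I_J + I_A)/N}, \eqn{\lambda_A = \beta_A (I_J +
#' I_A)/N}. Juveniles and adults are equally infectious; only susceptibility
#' differs. The frequency-dependent case with `N = 0` returns `(0, 0)`: an
#' empty population transmits nothing.
#'
#' @param infected_J,infected_A Infected juvenile/adult densities.
#' @param N Total host density (must be at least `infected_J + infected_A`).
#' @param beta_J Juvenile transmission coefficient.
#' @param params A [model_params()] object (supplies `beta_A` and the
#'   transmission mode).
#' @return Named numeric vector `c(lambda_J, lambda_A)`.
#' @examples
#' p <- preset_params("fig1")
#' forces_of_infection(6, 4, 100, 0.2, p)  # DD: lambda_J = 0.2 * 10
#' @export
forces_of_infection <- function(infected_J, infected_A, N, beta_J, params) {
  stopifnot(inherits(params, "jsev_params"))
  if (infected_J < 0 || infected_A < 0 || N < 0)
    stop("densities must be non-negative")
  itot <- infected_J + infected_A
  if (N + 1e-9 * max(1, N) < itot)
    stop("N must be at least the total infected density")
  scale <- if (params$transmission_mode == "density_dependent") 1
           else if (N > 0) 1 / N else 0
  c(lambda_J = beta_J * itot * scale,
    lambda_A = params$beta_A * itot * scale)
}

# Internal clipped RHS used by integrators. `y` is the 4-vector
# (S_J, S_A, I_J, I_A); small negative values from floating-point integration
# are clipped to zero; anything below -neg_tol indicates integrator failure.
.rhs_core <- function(y, beta_J, params, a = NULL, g = NULL) {
  neg <- min(y, 0)
  if (neg < -1e-6 * max(1, max(abs(y))))
    stop("integration produced strongly negative densities")
  y <- pmax(y, 0)
  S_J <- y[1]; S_A <- y[2]; I_J <- y[3]; I_A <- y[4]
  N <- S_J + S_A + I_J + I_A
  if (is.null(a)) {
    tr <- tradeoff_value(beta_J, params)
    a <- tr$a; g <- tr$g
  }
  itot <- I_J + I_A
  scale <- if (params$transmission_mode == "density_dependent") 1
           else if (N > 0) 1 / N else 0
  lJ <- beta_J * itot * scale
  lA <- params$beta_A * itot * scale
  Gam <- params$Gamma
  births <- a * (S_A + params$f * I_A) * (1 - params$q * N)
  c(births - (params$b + g) * S_J - lJ * S_J + params$gamma * I_J,
    g * S_J - params$b * S_A - lA * S_A + params$gamma * I_A,
    lJ * S_J - (Gam + g) * I_J,
    lA * S_A + g * I_J - Gam * I_A)
}

#' Right-hand side of the single-strain model
#'
#' The epidemiological dynamics of a monomorphic host population:
#' \deqn{\dot S_J = a(\beta_J)(S_A + f I_A)(1 - qN) - (b + g(\beta_J)) S_J
#'       - \lambda_J S_J + \gamma I_J}
#' \deqn{\dot S_A = g(\beta_J) S_J - b S_A - \lambda_A S_A + \gamma I_A}
#' \deqn{\dot I_J = \lambda_J S_J - (\Gamma + g(\beta_J)) I_J}
#' \deqn{\dot I_A = \lambda_A S_A + g(\beta_J) I_J - \Gamma I_A}
#' with \eqn{\Gamma = b + \alpha + \gamma}. Reproduction comes only from
#' adults (infected adults at relative fecundity `f`), is reduced by
#' competition `1 - qN`, and recruits into `S_J`. Both susceptible and
#' infected juveniles mature at the trait-dependent rate `g(beta_J)`; recovery
#' returns hosts to the susceptible class of their current stage.
#'
#' @param state A [population_state()] (or 4-vector S_J, S_A, I_J, I_A).
#' @param beta_J Trait value in `[beta_A, d * beta_A]`.
#' @param params A [model_params()] object.
#' @return Named numeric vector of the four time-derivatives.
#' @export
ode_rhs <- function(state, beta_J, params) {
  stopifnot(inherits(params, "jsev_params"))
  y <- unclass(state)[1:4]
  out <- .rhs_core(y, beta_J, params)
  names(out) <- c("S_J", "S_A", "I_J", "I_A")
  out
}

# Internal vectorised multi-strain RHS on a 4 x k state matrix.
.multi_rhs_core <- function(states, beta_J, params, a = NULL, g = NULL) {
  states <- pmax(states, 0)
  N <- sum(states)
  itot <- sum(states[3, ]) + sum(states[4, ])
  if (is.null(a)) {
    tr <- tradeoff_value(beta_J, params)
    a <- tr$a; g <- tr$g
  }
  scale <- if (params$transmission_mode == "density_dependent") 1
           else if (N > 0) 1 / N else 0
  lJ <- beta_J * itot * scale
  lA <- params$beta_A * itot * scale
  Gam <- params$Gamma
  S_J <- states[1, ]; S_A <- states[2, ]; I_J <- states[3, ]; I_A <- states[4, ]
  births <- a * (S_A + params$f * I_A) * (1 - params$q * N)
  rbind(births - (params$b + g) * S_J - lJ * S_J + params$gamma * I_J,
        g * S_J - params$b * S_A - lA * S_A + params$gamma * I_A,
        lJ * S_J - (Gam + g) * I_J,
        lA * S_A + g * I_J - Gam * I_A)
}

#' Right-hand side of the multi-strain model
#'
#' Each genotype follows the single-strain equations with its own trait and
#' trade-off rates; density-dependent competition acts through the total
#' density over all strains, and the forces of infection use the total
#' infected density over all strains (juvenile and adult infecteds are equally
#' infectious regardless of genotype). With a single strain this reduces
#' exactly to [ode_rhs()].
#'
#' @param strains A [strain_set()].
#' @param params A [model_params()] object.
#' @return A 4 x k matrix of time-derivatives (rows S_J, S_A, I_J, I_A).
#' @export
multistrain_rhs <- function(strains, params) {
  stopifnot(inherits(strains, "jsev_strainset"), inherits(params, "jsev_params"))
  if (length(strains$beta_J) < 1) stop("empty strain set")
  out <- .multi_rhs_core(strains$states, strains$beta_J, params)
  rownames(out) <- c("S_J", "S_A", "I_J", "I_A")
  out
}

# Integrate the single-strain model with lsoda. Returns the deSolve matrix.
.integrate <- function(y0, beta_J, params, times, rtol = 1e-8, atol = 1e-10) {
  tr <- tradeoff_value(beta_J, params)
  fun <- function(t, y, parms) list(.rhs_core(y, beta_J, params,
                                              a = tr$a, g = tr$g))
  deSolve::lsoda(pmax(y0, 0), times, fun, parms = NULL,
                 rtol = rtol, atol = atol)
}
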