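# Shared fixtures: the base qualitative-outcome parameterization and a
# random generator of admissible, demographically viable parameter sets used
# by the property-style tests.

fig1 <- function(...) {
  p <- preset_params("fig1")
  if (...length()) p <- update_params(p, ...)
  p
}

# Draw a random admissible parameter set with a viable disease-free host.
# Rates span the neighbourhood of the study parameterizations; both
# trade-off targets and both transmission modes are exercised.
draw_admissible <- function() {
  repeat {
    q <- 0.001
    a0 <- stats::runif(1, 1.5, 6)
    b <- stats::runif(1, 0.05, 0.5)
    g0 <- stats::runif(1, 0.1, 1)
    f <- stats::runif(1, 0.5, 1)
    alpha <- stats::runif(1, 0.1, 1)
    gam <- stats::runif(1, 0.1, 1)
    d <- stats::runif(1, 2, 4)
    mode <- sample(c("density_dependent", "frequency_dependent"), 1)
    beta_A <- if (mode == "density_dependent") stats::runif(1, 1, 4) * q
              else stats::runif(1, 0.5, 2.5)
    p <- model_params(a0 = a0, b = b, g0 = g0, q = q, f = f, alpha = alpha,
                      gamma = gam, beta_A = beta_A, d = d,
                      tradeoff_target = sample(c("reproduction",
                                                 "maturation"), 1),
                      c_strength = stats::runif(1, 0, 1.5),
                      c_shape = stats::runif(1, -3, 3),
                      transmission_mode = mode)
    if (a0 * g0 > b * (b + g0)) return(p)
  }
}

# Attracting resident equilibrium as a plain state, or NULL when the
# population is extinct or did not converge.
resident_state <- function(beta_J, params) {
  eq <- tryCatch(juvsus:::.resident_equilibrium(beta_J, params),
                 error = function(e) NULL)
  if (is.null(eq) || eq$extinct || !eq$converged) return(NULL)
  population_state(eq$state[1], eq$state[2], eq$state[3], eq$state[4])
}
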