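#' Model parameters for the stage-structured SIS host-parasite model
#'
#' Constructs and validates the full parameter set of the model: host
#' demography, epidemiology, the susceptibility trade-off, and the mode of
#' transmission. Juveniles are always at least as susceptible as adults and at
#' most `d` times more susceptible, so the evolving trait (the juvenile
#' transmission coefficient `beta_J`) lives on `[beta_A, d * beta_A]`.
#'
#' Exactly one trade-off is active at a time: elevated juvenile susceptibility
#' buys either a higher adult reproduction rate (`tradeoff_target =
#' "reproduction"`) or a higher maturation rate (`"maturation"`). The inactive
#' trait keeps its baseline rate (its strength constant is implicitly zero).
#'
#' @param a0 Baseline adult reproduction rate (per unit time).
#' @param b Natural mortality rate, age-independent (per unit time); `1/b` is
#'   the average lifespan of a disease-free host.
#' @param g0 Baseline maturation rate (per unit time); `g0/(b + g0)` is the
#'   baseline probability of reaching the adult stage.
#' @param q Density-dependent competition coefficient (per unit density);
#'   reproduction is reduced by the factor `1 - q * N`.
#' @param f Relative fecundity of infected hosts, in `[0, 1]`.
#' @param alpha Disease-induced mortality rate (per unit time).
#' @param gamma Recovery rate, no immunity (per unit time).
#' @param beta_A Adult transmission coefficient (per density per time under
#'   density-dependent transmission; per time under frequency-dependent
#'   transmission).
#' @param d Maximum fold-elevation of juvenile over adult susceptibility
#'   (dimensionless, `>= 1`).
#' @param tradeoff_target `"reproduction"` or `"maturation"`.
#' @param c_strength Trade-off strength: the active rate reaches
#'   `baseline * (1 + c_strength)` at `beta_J = d * beta_A`.
#' @param c_shape Trade-off shape: negative values give diminishing returns
#'   (accelerating costs), positive values increasing returns (decelerating
#'   costs), zero a linear trade-off.
#' @param transmission_mode `"density_dependent"` or `"frequency_dependent"`.
#'
#' @return An object of class `jsev_params`: a validated list with the above
#'   fields plus read-only derived quantities `Gamma = b + alpha + gamma` (the
#'   reciprocal of the infectious period), `lifespan = 1/b` and
#'   `maturation_probability = g0/(b + g0)`.
#'
#' @examples
#' p <- model_params(a0 = 2, b = 0.1, g0 = 0.25, q = 0.001, f = 0.75,
#'                   alpha = 0.5, gamma = 0.5, beta_A = 0.002, d = 3,
#'                   tradeoff_target = "reproduction",
#'                   c_strength = 0.4, c_shape = -1.5)
#' p$Gamma
#' p$maturation_probability
#' @export
model_params <- function(a0, b, g0, q, f, alpha, gamma, beta_A, d,
                         tradeoff_target = c("reproduction", "maturation"),
                         c_strength = 0, c_shape = 0,
                         transmission_mode = c("density_dependent",
                                               "frequency_dependent")) {
  tradeoff_target <- match.arg(tradeoff_target)
  transmission_mode <- match.arg(transmission_mode)
  num <- c(a0 = a0, b = b, g0 = g0, q = q, f = f, alpha = alpha,
           gamma = gamma, beta_A = beta_A, d = d,
           c_strength = c_strength, c_shape = c_shape)
  if (!all(is.finite(num)))
    stop("all numeric parameters must be finite")
  nonneg <- c("a0", "b", "g0", "q", "alpha", "gamma", "beta_A", "c_strength")
  bad <- nonneg[num[nonneg] < 0]
  if (length(bad))
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "))
  if (b <= 0) stop("b must be strictly positive")
  if (q <= 0) stop("q must be strictly positive")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (d < 1) stop("d must be >= 1 so the trait interval is non-empty")

  p <- list(a0 = a0, b = b, g0 = g0, q = q, f = f, alpha = alpha,
            gamma = gamma, beta_A = beta_A, d = d,
            tradeoff_target = tradeoff_target,
            c_strength = c_strength, c_shape = c_shape,
            transmission_mode = transmission_mode,
            Gamma = b + alpha + gamma,
            lifespan = 1 / b,
            maturation_probability = g0 / (b + g0))
  class(p) <- "jsev_params"
  p
}

#' @export
print.jsev_params <- function(x, ...) {
  cat("Stage-structured SIS model parameters\n")
  cat(sprintf("  demography:   a0 = %g, b = %g (lifespan %.3g), g0 = %g (maturation prob %.3g), q = %g\n",
              x$a0, x$b, x$lifespan, x$g0, x$maturation_probability, x$q))
  cat(sprintf("  epidemiology: beta_A = %g, alpha = %g, gamma = %g, f = %g, Gamma = %g\n",
              x$beta_A, x$alpha, x$gamma, x$f, x$Gamma))
  cat(sprintf("  trait:        beta_J in [%g, %g] (d = %g)\n",
              x$beta_A, x$d * x$beta_A, x$d))
  cat(sprintf("  trade-off:    %s, strength %g, shape %g (%s)\n",
              x$tradeoff_target, x$c_strength, x$c_shape,
              if (x$c_shape < 0) "diminishing returns"
              else if (x$c_shape > 0) "increasing returns" else "linear"))
  cat(sprintf("  transmission: %s\n", x$transmission_mode))
  invisible(x)
}

#' Update fields of a parameter set
#'
#' Returns a new validated [model_params()] object with the given fields
#' replaced. Derived quantities are recomputed.
#'
#' @param params A `jsev_params` object.
#' @param ... Named fields to replace.
#' @return A new `jsev_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "jsev_params"))
  new <- list(...)
  keep <- c("a0", "b", "g0", "q", "f", "alpha", "gamma", "beta_A", "d",
            "tradeoff_target", "c_strength", "c_shape", "transmission_mode")
  unknown <- setdiff(names(new), keep)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  args <- params[keep]
  args[names(new)] <- new
  do.call(model_params, args)
}

#' Read model parameters from a flat key-value YAML config
#'
#' The file holds one flat mapping whose keys are the [model_params()]
#' arguments, optionally with a `preset` key naming a shipped preset whose
#' values are used as the base and then overridden by any further keys.
#' Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `jsev_params` object.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat key-value mapping")
  fields <- c("a0", "b", "g0", "q", "f", "alpha", "gamma", "beta_A", "d",
              "tradeoff_target", "c_strength", "c_shape", "transmission_mode")
  unknown <- setdiff(names(cfg), c(fields, "preset"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$preset)) {
    base <- preset_params(cfg$preset)
    cfg$preset <- NULL
    if (length(cfg)) base <- do.call(update_params, c(list(base), cfg))
    return(base)
  }
  do.call(model_params, cfg)
}

#' Named parameter presets for the published figure parameterizations
#'
#' Returns the parameter set used for the outcome-map and sweep analyses.
#' `"fig1"` is the base qualitative-outcome parameterization (density-dependent
#' transmission, a0 = 2); `"fig1c"`--`"fig1f"` pick trade-off constants in,
#' respectively, a CSS, repeller, branching and repeller-plus-branching cell of
#' its trade-off space. `"fig2"` (reproduction trade-off) and `"fig3"`
#' (maturation trade-off) are the quantitative sweep parameterizations
#' (a0 = 5, diminishing returns). `"fig4r"`/`"fig4m"` are the density-dependent
#' reference parameterizations used to calibrate the frequency-dependent
#' analyses for the reproduction and maturation trade-offs (the latter is the
#' preset exhibiting an evolutionary-suicide gap at short lifespans).
#'
#' @param name Preset name.
#' @return A `jsev_params` object.
#' @export
preset_params <- function(name = c("fig1", "fig1c", "fig1d", "fig1e", "fig1f",
                                   "fig2", "fig3", "fig4r", "fig4m")) {
  name <- match.arg(name)
  base <- list(a0 = 2, b = 0.1, g0 = 0.25, q = 0.001, f = 0.75,
               alpha = 0.5, gamma = 0.5, beta_A = 0.002, d = 3,
               tradeoff_target = "reproduction",
               c_strength = 0, c_shape = 0,
               transmission_mode = "density_dependent")
  mod <- switch(name,
    fig1  = list(),
    fig1c = list(c_strength = 0.4, c_shape = -1.5),
    fig1d = list(c_strength = 0.4, c_shape = -0.3),
    fig1e = list(c_strength = 0.4, c_shape = -0.7),
    fig1f = list(c_strength = 0.4, c_shape = -0.7),
    fig2  = list(a0 = 5, c_strength = 0.7, c_shape = -2),
    fig3  = list(a0 = 5, tradeoff_target = "maturation",
                 c_strength = 0.5, c_shape = -2),
    fig4r = list(a0 = 5, c_strength = 0.7, c_shape = -2),
    fig4m = list(a0 = 5, g0 = 0.1, beta_A = 0.004,
                 tradeoff_target = "maturation",
                 c_strength = 0.5, c_shape = -2))
  base[names(mod)] <- mod
  do.call(model_params, base)
}

#' Population state of the four epidemiological compartments
#'
#' @param S_J,S_A,I_J,I_A Non-negative densities of susceptible/infected
#'   juveniles and adults.
#' @return A named numeric vector of class `jsev_state` with components
#'   `S_J`, `S_A`, `I_J`, `I_A`.
#' @examples
#' s <- population_state(10, 30, 5, 5)
#' total_density(s)
#' @export
population_state <- function(S_J, S_A, I_J, I_A) {
  y <- c(S_J = S_J, S_A = S_A, I_J = I_J, I_A = I_A)
  if (!all(is.finite(y))) stop("densities must be finite")
  if (any(y < 0)) stop("densities must be non-negative")
  class(y) <- "jsev_state"
  y
}

#' Total host density N of a population state
#' @param state A `jsev_state` vector (or any 4-vector ordered S_J, S_A, I_J, I_A).
#' @return `S_J + S_A + I_J + I_A`.
#' @export
total_density <- function(state) sum(unclass(state)[1:4])

#' Multi-genotype strain set
#'
#' Bookkeeping container for the polymorphic simulations: a set of host
#' genotypes, each with its own juvenile transmission coefficient and its own
#' four-compartment state. Competition and infection act through totals over
#' all strains.
#'
#' @param beta_J Numeric vector of juvenile transmission coefficients, each in
#'   `[beta_A, d * beta_A]`.
#' @param states A 4 x k matrix (rows S_J, S_A, I_J, I_A) or a list of
#'   `jsev_state` vectors, one per genotype.
#' @param params A `jsev_params` object (used to validate the trait range).
#' @return An object of class `jsev_strainset`: list with `beta_J` and the
#'   4 x k `states` matrix.
#' @export
strain_set <- function(beta_J, states, params) {
  stopifnot(inherits(params, "jsev_params"))
  if (length(beta_J) < 1) stop("strain set must contain at least one strain")
  if (is.list(states)) states <- vapply(states, function(s) unclass(s)[1:4],
                                        numeric(4))
  states <- as.matrix(states)
  if (nrow(states) != 4 || ncol(states) != length(beta_J))
    stop("states must be a 4 x k matrix matching length(beta_J)")
  lo <- params$beta_A - 1e-12
  hi <- params$d * params$beta_A + 1e-12
  if (any(beta_J < lo | beta_J > hi))
    stop("every beta_J must lie in [beta_A, d * beta_A]")
  if (any(states < 0)) stop("strain densities must be non-negative")
  rownames(states) <- c("S_J", "S_A", "I_J", "I_A")
  structure(list(beta_J = as.numeric(beta_J), states = states),
            class = "jsev_strainset")
}
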