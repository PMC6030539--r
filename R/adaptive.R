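# Resident "environment" as felt by a rare mutant: the resident equilibrium
# collapsed to the quantities entering the mutant's linearised subsystem.
.environment_of <- function(state, params) {
  y <- unname(unclass(state)[1:4])
  N <- sum(y)
  itot <- y[3] + y[4]
  scale <- if (params$transmission_mode == "density_dependent") 1
           else if (N > 0) 1 / N else 0
  list(N = N, itot = itot, scale = scale,
       lambda_A = params$beta_A * itot * scale,
       P = 1 - params$q * N)
}

# Closed-form sign-equivalent invasion fitness: minus the determinant of the
# mutant's 4x4 linearised subsystem at the resident equilibrium. Factored
# form (D_m = g_m + Gamma - gamma):
#   w = a_m P g_m [ (Gamma + f lA)(Gamma + g_m) + l_m (gamma + f (b + lA)) ]
#       - [ Gamma b + (Gamma - gamma) lA ] [ (Gamma + g_m)(b + g_m) + l_m D_m ]
# Vectorised over beta_m.
.fitness_analytic <- function(beta_m, env, params) {
  tr <- tradeoff_value(beta_m, params)
  am <- tr$a; gm <- tr$g
  lm <- beta_m * env$itot * env$scale
  lA <- env$lambda_A
  b <- params$b; f <- params$f; gam <- params$gamma; Gam <- params$Gamma
  Dm <- gm + Gam - gam
  K <- (Gam + f * lA) * (Gam + gm) + lm * (gam + f * (b + lA))
  B <- Gam * b + (Gam - gam) * lA
  am * env$P * gm * K - B * ((Gam + gm) * (b + gm) + lm * Dm)
}

# Analytic selection gradient: exact derivative of .fitness_analytic in the
# mutant trait, via the chain rule through a(beta), g(beta) and lambda(beta).
.gradient_analytic <- function(beta, env, params) {
  tr <- tradeoff_value(beta, params, deriv = TRUE)
  am <- tr$a; gm <- tr$g
  lm <- beta * env$itot * env$scale
  dlm <- env$itot * env$scale
  lA <- env$lambda_A
  b <- params$b; f <- params$f; gam <- params$gamma; Gam <- params$Gamma
  Dm <- gm + Gam - gam
  K <- (Gam + f * lA) * (Gam + gm) + lm * (gam + f * (b + lA))
  B <- Gam * b + (Gam - gam) * lA
  dw_da <- env$P * gm * K
  dw_dg <- am * env$P * K + am * env$P * gm * (Gam + f * lA) -
    B * ((b + gm) + (Gam + gm) + lm)
  dw_dl <- am * env$P * gm * (gam + f * (b + lA)) - B * Dm
  dw_da * tr$da + dw_dg * tr$dg + dw_dl * dlm
}

# The mutant's linearised 4x4 subsystem matrix (Metzler, irreducible for
# positive rates); its dominant eigenvalue is the independent fitness oracle.
.mutant_matrix <- function(beta_m, env, params) {
  tr <- tradeoff_value(beta_m, params)
  am <- tr$a; gm <- tr$g
  lm <- beta_m * env$itot * env$scale
  lA <- env$lambda_A
  b <- params$b; f <- params$f; gam <- params$gamma; Gam <- params$Gamma
  matrix(c(-(b + gm + lm), am * env$P, gam, am * f * env$P,
           gm, -(b + lA), 0, gam,
           lm, 0, -(Gam + gm), 0,
           0, lA, gm, -Gam),
         nrow = 4, byrow = TRUE)
}

# Resolve the resident equilibrium argument used by the fitness functions:
# accept a jsev_equilibrium, a raw state, or NULL (computed on the fly).
.resolve_resident <- function(beta_resident, params, resident) {
  if (is.null(resident)) {
    eq <- .resident_equilibrium(beta_resident, params)
    if (eq$extinct)
      stop("resident population is extinct: no environment to invade")
    return(eq$state)
  }
  if (inherits(resident, "jsev_equilibrium")) {
    if (resident$classification == "extinct")
      stop("resident population is extinct: no environment to invade")
    return(unclass(resident$state)[1:4])
  }
  y <- unclass(resident)[1:4]
  if (sum(y) < 1e-8)
    stop("resident population is extinct: no environment to invade")
  y
}

#' Invasion fitness of a rare mutant
#'
#' Sign-equivalent invasion fitness of a rare mutant with trait `beta_mutant`
#' in the environment set by a resident with trait `beta_resident` at its
#' ecological equilibrium. The `"analytic"` method evaluates the closed-form
#' proxy (minus the determinant of the mutant's linearised subsystem, which
#' vanishes exactly at neutrality and has the sign of the dominant
#' eigenvalue); the `"eigenvalue"` method computes that dominant eigenvalue
#' directly and serves as the independent oracle.
#'
#' @param beta_mutant,beta_resident Trait values in `[beta_A, d * beta_A]`.
#' @param params A [model_params()] object.
#' @param method `"analytic"` (default) or `"eigenvalue"`.
#' @param resident Optional precomputed resident equilibrium (a
#'   `jsev_equilibrium` or state vector); computed if omitted.
#' @return Signed fitness proxy (`> 0`: the mutant can invade). Vectorised
#'   over `beta_mutant`.
#' @export
invasion_fitness <- function(beta_mutant, beta_resident, params,
                             method = c("analytic", "eigenvalue"),
                             resident = NULL) {
  stopifnot(inherits(params, "jsev_params"))
  method <- match.arg(method)
  state <- .resolve_resident(beta_resident, params, resident)
  env <- .environment_of(state, params)
  if (method == "analytic") {
    .fitness_analytic(beta_mutant, env, params)
  } else {
    vapply(beta_mutant, function(bm) {
      ev <- eigen(.mutant_matrix(bm, env, params), only.values = TRUE)$values
      max(Re(ev))
    }, numeric(1))
  }
}

#' Selection gradient on juvenile susceptibility
#'
#' The derivative of invasion fitness with respect to the mutant trait,
#' evaluated at the resident value, computed in closed form (chain rule
#' through the trade-off and the force of infection). Evolution proceeds in
#' the direction of the gradient until a singular strategy or a trait
#' boundary is reached.
#'
#' @inheritParams invasion_fitness
#' @return Signed gradient (vectorised over `beta_resident` only when a
#'   common `resident` is supplied for a single resident value; otherwise a
#'   fresh equilibrium is computed per value).
#' @export
selection_gradient <- function(beta_resident, params, resident = NULL) {
  stopifnot(inherits(params, "jsev_params"))
  if (length(beta_resident) > 1 && is.null(resident)) {
    return(vapply(beta_resident,
                  function(b) selection_gradient(b, params), numeric(1)))
  }
  state <- .resolve_resident(beta_resident, params, resident)
  env <- .environment_of(state, params)
  .gradient_analytic(beta_resident, env, params)
}

# Gradient along a trait grid with warm-started equilibrium continuation.
# Returns data.frame(beta, gradient, ok, extinct) plus the list of states.
.gradient_profile <- function(params, grid) {
  n <- length(grid)
  gradient <- rep(NA_real_, n)
  ok <- rep(FALSE, n); extinct <- rep(FALSE, n)
  states <- vector("list", n)
  guess <- NULL
  for (i in seq_len(n)) {
    eq <- .resident_equilibrium(grid[i], params, guess = guess)
    if (eq$extinct) { extinct[i] <- TRUE; next }
    if (!eq$converged) next
    states[[i]] <- eq$state
    guess <- eq$state
    env <- .environment_of(eq$state, params)
    gradient[i] <- .gradient_analytic(grid[i], env, params)
    ok[i] <- TRUE
  }
  list(df = data.frame(beta = grid, gradient = gradient,
                       ok = ok, extinct = extinct),
       states = states)
}

# Normalised-curvature ES test at a candidate singular point.
# Returns list(curvature, marginal). Curvature is d2w/du2 with
# u = (beta - beta_A)/((d-1) beta_A).
.es_curvature <- function(beta_star, env, params, h_u = 1e-4) {
  span <- params$beta_A * (params$d - 1)
  h <- h_u * span
  lo <- params$beta_A; hi <- params$d * params$beta_A
  bm <- pmin(pmax(c(beta_star - h, beta_star, beta_star + h), lo), hi)
  w <- .fitness_analytic(bm, env, params)
  curv <- (w[1] - 2 * w[2] + w[3]) / h_u^2
  list(curvature = curv, marginal = abs(curv) < 1e-7)
}

#' Locate and classify singular strategies
#'
#' Scans the selection gradient on a uniform trait grid (with warm-started
#' equilibrium continuation), refines every sign change by bisection, and
#' classifies each root: evolutionarily stable (ES) from the second
#' derivative of invasion fitness in the mutant direction, convergence stable
#' (CS) from the gradient's sign on either side of the root. Labels follow
#' the usual taxonomy: CSS (ES and CS), branching point (CS, not ES),
#' repeller (neither), garden of Eden (ES, not CS). Boundary attractors
#' (gradient pointing into `beta_A` or `d * beta_A`) are reported separately.
#'
#' @param params A [model_params()] object.
#' @param grid_n Number of grid points (default 201, minimum 16).
#' @return An object of class `jsev_singular`: list with `strategies` (data
#'   frame: `beta_J_star`, `is_ES`, `is_CS`, `marginal`, `label`,
#'   `curvature`), `endpoints` (logical `min_attracting`, `max_attracting`),
#'   `profile` (the gradient grid) and `excluded` (count of non-convergent
#'   grid points).
#' @export
find_singular_strategies <- function(params, grid_n = 201) {
  stopifnot(inherits(params, "jsev_params"), grid_n >= 16)
  lo <- params$beta_A; hi <- params$d * params$beta_A
  span <- hi - lo
  if (span <= 0)
    return(structure(list(strategies = data.frame(), endpoints = c(
      min_attracting = FALSE, max_attracting = FALSE),
      profile = NULL, excluded = 0L, params = params),
      class = "jsev_singular"))
  grid <- seq(lo, hi, length.out = grid_n)
  prof <- .gradient_profile(params, grid)
  df <- prof$df
  excluded <- sum(!df$ok)
  if (excluded > 0 && excluded == grid_n)
    stop("no convergent resident equilibria on the trait grid")

  idx <- which(df$ok)
  roots <- list()
  gfun_cache_guess <- NULL
  gfun <- function(b, guess) {
    eq <- .resident_equilibrium(b, params, guess = guess)
    if (eq$extinct || !eq$converged) return(NA_real_)
    env <- .environment_of(eq$state, params)
    .gradient_analytic(b, env, params)
  }
  for (k in seq_len(length(idx) - 1)) {
    i <- idx[k]; j <- idx[k + 1]
    if (j != i + 1) next                      # gap of excluded points
    gi <- df$gradient[i]; gj <- df$gradient[j]
    if (!is.finite(gi) || !is.finite(gj) || sign(gi) * sign(gj) >= 0) next
    guess <- prof$states[[i]]
    root <- tryCatch(
      stats::uniroot(function(b) gfun(b, guess), c(grid[i], grid[j]),
                     tol = 1e-8 * span)$root,
      error = function(e) NA_real_)
    if (!is.finite(root)) next
    eq <- .resident_equilibrium(root, params, guess = guess)
    if (eq$extinct) next
    env <- .environment_of(eq$state, params)
    es <- .es_curvature(root, env, params)
    epsb <- 1e-4 * span
    g_lo <- gfun(max(root - epsb, lo), eq$state)
    g_hi <- gfun(min(root + epsb, hi), eq$state)
    is_CS <- isTRUE(g_lo > 0 && g_hi < 0)
    is_ES <- es$curvature < 0
    label <- if (es$marginal) "marginal"
             else if (is_ES && is_CS) "CSS"
             else if (is_CS) "branching_point"
             else if (is_ES) "garden_of_eden"
             else "repeller"
    roots[[length(roots) + 1]] <- data.frame(
      beta_J_star = root, is_ES = is_ES, is_CS = is_CS,
      marginal = es$marginal, label = label, curvature = es$curvature)
  }
  strategies <- if (length(roots)) do.call(rbind, roots)
                else data.frame(beta_J_star = numeric(0), is_ES = logical(0),
                                is_CS = logical(0), marginal = logical(0),
                                label = character(0), curvature = numeric(0))
  strategies <- strategies[order(strategies$beta_J_star), , drop = FALSE]
  g_first <- df$gradient[idx[1]]
  g_last <- df$gradient[idx[length(idx)]]
  endpoints <- c(min_attracting = isTRUE(g_first < 0),
                 max_attracting = isTRUE(g_last > 0))
  structure(list(strategies = strategies, endpoints = endpoints,
                 profile = df, excluded = excluded, params = params),
            class = "jsev_singular")
}

#' @export
print.jsev_singular <- function(x, ...) {
  cat("Singular strategies on [beta_A, d*beta_A]\n")
  if (nrow(x$strategies) == 0) cat("  (no interior singular strategy)\n")
  else {
    s <- x$strategies
    for (i in seq_len(nrow(s)))
      cat(sprintf("  beta_J* = %.6g (ratio %.3f): %s (ES=%s, CS=%s)\n",
                  s$beta_J_star[i], s$beta_J_star[i] / x$params$beta_A,
                  s$label[i], s$is_ES[i], s$is_CS[i]))
  }
  cat(sprintf("  endpoint attractors: beta_A %s, d*beta_A %s\n",
              if (x$endpoints["min_attracting"]) "attracting" else "-",
              if (x$endpoints["max_attracting"]) "attracting" else "-"))
  if (x$excluded > 0)
    cat(sprintf("  (%d non-convergent grid points excluded)\n", x$excluded))
  invisible(x)
}

#' Classify the qualitative evolutionary outcome at one trade-off point
#'
#' Maps the set of interior singular strategies and endpoint attractors to
#' one qualitative outcome label: `MN` (minimum susceptibility), `MX`
#' (maximum), `CSS`, `RE` (repeller), `BR` (branching point), `RE_BR`,
#' `RE_CSS`, or `other` for configurations outside the enumerated patterns.
#'
#' @param params A [model_params()] object.
#' @param grid_n Grid resolution passed to [find_singular_strategies()].
#' @param sing Optional precomputed `jsev_singular`.
#' @return A character label.
#' @export
classify_tradeoff_point <- function(params, grid_n = 201, sing = NULL) {
  if (is.null(sing)) sing <- find_singular_strategies(params, grid_n)
  s <- sing$strategies
  labs <- s$label[!s$marginal]
  if (any(s$marginal)) return("other")
  if (length(labs) == 0) {
    g <- sing$profile$gradient[sing$profile$ok]
    if (all(g <= 0)) return("MN")
    if (all(g >= 0)) return("MX")
    return("other")
  }
  key <- paste(sort(labs), collapse = "+")
  switch(key,
         "CSS" = "CSS",
         "repeller" = "RE",
         "branching_point" = "BR",
         "branching_point+repeller" = "RE_BR",
         "CSS+repeller" = "RE_CSS",
         "other")
}

#' Map qualitative outcomes over trade-off space
#'
#' Classifies every (strength, shape) cell of a trade-off grid, producing the
#' qualitative outcome map over trade-off space.
#'
#' @param params Base [model_params()] (its `c_strength`/`c_shape` are
#'   replaced cell by cell).
#' @param strength_grid,shape_grid Numeric grids (non-empty).
#' @param grid_n Trait-grid resolution per cell.
#' @return An object of class `jsev_map`: list with `labels` (matrix,
#'   strength x shape), `strength`, `shape`, `params`.
#' @export
tradeoff_space_map <- function(params, strength_grid, shape_grid,
                               grid_n = 201) {
  stopifnot(length(strength_grid) >= 1, length(shape_grid) >= 1)
  labels <- matrix(NA_character_, length(strength_grid), length(shape_grid),
                   dimnames = list(signif(strength_grid, 6),
                                   signif(shape_grid, 6)))
  for (i in seq_along(strength_grid))
    for (j in seq_along(shape_grid)) {
      p <- update_params(params, c_strength = strength_grid[i],
                         c_shape = shape_grid[j])
      labels[i, j] <- tryCatch(classify_tradeoff_point(p, grid_n),
                               error = function(e) "invalid")
    }
  structure(list(labels = labels, strength = strength_grid,
                 shape = shape_grid, params = params),
            class = "jsev_map")
}

#' @export
print.jsev_map <- function(x, ...) {
  cat(sprintf("Trade-off space outcome map (%d strength x %d shape), target: %s\n",
              length(x$strength), length(x$shape), x$params$tradeoff_target))
  print(x$labels)
  invisible(x)
}

#' @export
as.data.frame.jsev_map <- function(x, ...) {
  expand <- expand.grid(strength = x$strength, shape = x$shape,
                        KEEP.OUT.ATTRS = FALSE)
  expand$label <- as.vector(x$labels)
  expand
}

#' Pairwise invasibility plot (sign matrix)
#'
#' Sign of the invasion fitness over a (resident, mutant) trait grid. The
#' diagonal is zero by neutrality; entry `[r, m]` is the sign of
#' `invasion_fitness(m, r)`.
#'
#' @param params A [model_params()] object.
#' @param grid_n Grid size (minimum 16).
#' @return An object of class `jsev_pip`: list with `beta` (grid), `sign`
#'   (grid_n x grid_n matrix, residents in rows), `fitness` (raw values).
#' @export
pairwise_invasibility <- function(params, grid_n = 101) {
  stopifnot(inherits(params, "jsev_params"), grid_n >= 16)
  lo <- params$beta_A; hi <- params$d * params$beta_A
  beta <- seq(lo, hi, length.out = grid_n)
  fit <- matrix(NA_real_, grid_n, grid_n)
  guess <- NULL
  for (i in seq_len(grid_n)) {
    eq <- .resident_equilibrium(beta[i], params, guess = guess)
    if (eq$extinct) next
    guess <- eq$state
    env <- .environment_of(eq$state, params)
    fit[i, ] <- .fitness_analytic(beta, env, params)
  }
  sg <- sign(fit)
  sg[abs(fit) < 1e-10] <- 0
  structure(list(beta = beta, sign = sg, fitness = fit, params = params),
            class = "jsev_pip")
}
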