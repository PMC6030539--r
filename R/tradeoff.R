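#' Susceptibility trade-off: reproduction or maturation benefit
#'
#' Maps the juvenile transmission coefficient `beta_J` to the pair of
#' life-history rates (reproduction `a`, maturation `g`). The active trait
#' follows
#' \deqn{r(\beta_J) = r_0 (1 + z(\beta_J)), \quad
#'       z(\beta_J) = c_1 \frac{1 - e^{c_2 x}}{1 - e^{c_2}}, \quad
#'       x = \frac{\beta_J - \beta_A}{\beta_A (d - 1)} \in [0, 1],}
#' with the linear limit \eqn{z = c_1 x} at \eqn{c_2 = 0}. The benefit is zero
#' at `beta_J = beta_A` and maximal, `r0 * (1 + c_strength)`, at
#' `beta_J = d * beta_A`. Negative `c_shape` gives diminishing returns
#' (accelerating costs), positive `c_shape` increasing returns. The inactive
#' rate stays at its baseline.
#'
#' @param beta_J Trait value(s) in `[beta_A, d * beta_A]` (vectorised).
#' @param params A [model_params()] object.
#' @param deriv If `TRUE`, also return the derivatives `da`, `dg` of the two
#'   rates with respect to `beta_J`.
#' @return A list with numeric components `a` and `g` (and `da`, `dg` when
#'   `deriv = TRUE`), each the length of `beta_J`.
#' @examples
#' p <- preset_params("fig1c")
#' tradeoff_value(p$beta_A, p)           # baseline rates
#' tradeoff_value(p$d * p$beta_A, p)$a   # a0 * (1 + c_strength)
#' @export
tradeoff_value <- function(beta_J, params, deriv = FALSE) {
  stopifnot(inherits(params, "jsev_params"))
  lo <- params$beta_A
  hi <- params$d * params$beta_A
  eps <- 1e-9 * max(hi, 1)
  if (any(beta_J < lo - eps | beta_J > hi + eps))
    stop("beta_J outside the admissible interval [beta_A, d * beta_A]")
  beta_J <- pmin(pmax(beta_J, lo), hi)

  span <- params$beta_A * (params$d - 1)
  if (span <= 0) {               # d == 1: degenerate interval, no benefit
    z <- rep(0, length(beta_J)); dz <- rep(0, length(beta_J))
  } else {
    x <- (beta_J - lo) / span
    c1 <- params$c_strength
    c2 <- params$c_shape
    if (abs(c2) < 1e-12) {
      z <- c1 * x
      dz <- rep(c1 / span, length(x))
    } else {
      denom <- 1 - exp(c2)
      z <- c1 * (1 - exp(c2 * x)) / denom
      dz <- c1 * (-c2 * exp(c2 * x)) / denom / span
    }
  }
  a <- rep(params$a0, length(beta_J)); da <- rep(0, length(beta_J))
  g <- rep(params$g0, length(beta_J)); dg <- rep(0, length(beta_J))
  if (params$tradeoff_target == "reproduction") {
    a <- params$a0 * (1 + z); da <- params$a0 * dz
  } else {
    g <- params$g0 * (1 + z); dg <- params$g0 * dz
  }
  out <- list(a = a, g = g)
  if (deriv) { out$da <- da; out$dg <- dg }
  out
}
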