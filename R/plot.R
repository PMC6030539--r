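#' Plot a pairwise invasibility plot
#'
#' Residents on the x axis, mutants on the y axis; shaded where the mutant
#' can invade (positive invasion fitness).
#'
#' @param x A `jsev_pip` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.jsev_pip <- function(x, ...) {
  graphics::image(x$beta, x$beta, t(x$sign), useRaster = TRUE,
                  col = c("white", "grey85", "grey30"),
                  breaks = c(-1.5, -0.5, 0.5, 1.5),
                  xlab = expression(beta[J] ~ "(resident)"),
                  ylab = expression(beta[J] ~ "(mutant)"),
                  main = "Pairwise invasibility", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Plot a trade-off space outcome map
#'
#' Strength on the x axis, shape on the y axis, one colour per qualitative
#' outcome label.
#'
#' @param x A `jsev_map` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.jsev_map <- function(x, ...) {
  levs <- c("MN", "MX", "CSS", "RE", "BR", "RE_BR", "RE_CSS", "other",
            "invalid")
  cols <- c("#4575b4", "#d73027", "#91cf60", "#fee090", "#984ea3",
            "#ff7f00", "#a65628", "grey80", "grey50")
  z <- matrix(match(x$labels, levs), nrow(x$labels), ncol(x$labels))
  graphics::image(x$strength, x$shape, z, col = cols, zlim = c(1, 9),
                  xlab = "trade-off strength", ylab = "trade-off shape",
                  main = sprintf("Qualitative outcomes (%s trade-off)",
                                 x$params$tradeoff_target), ...)
  present <- levs[sort(unique(as.vector(z)))]
  graphics::legend("topright", legend = present,
                   fill = cols[match(present, levs)], cex = 0.8, bg = "white")
  invisible(x)
}

#' Plot an evolutionary trajectory as a trait-time heat map
#'
#' Evolutionary time on the x axis, trait on the y axis, shading by host
#' abundance; singular strategies can be overlaid as dashed lines.
#'
#' @param x A `jsev_evo` object.
#' @param singular Optional `jsev_singular` whose `beta_J_star` values are
#'   drawn as dashed horizontal lines.
#' @param ... Passed to [graphics::image()].
#' @export
plot.jsev_evo <- function(x, singular = NULL, ...) {
  ab <- x$abundance
  ab[ab <= 0] <- NA
  graphics::image(x$epoch_times, x$trait_lattice, log10(ab), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "evolutionary time (epochs)",
                  ylab = expression(beta[J]),
                  main = sprintf("Trait evolution (outcome: %s)", x$outcome),
                  ...)
  if (!is.null(singular) && nrow(singular$strategies))
    graphics::abline(h = singular$strategies$beta_J_star, lty = 2)
  invisible(x)
}

#' Plot a sweep result
#'
#' Three stacked panels against the axis quantity: evolved trait ratio,
#' prevalence (evolved and initial), and juvenile fraction (evolved and
#' initial), mirroring the standard presentation of these experiments.
#'
#' @param x A `jsev_sweep` object.
#' @param ... Unused.
#' @export
plot.jsev_sweep <- function(x, ...) {
  r <- x$records
  xl <- if (x$axis == "lifespan") "host lifespan 1/b"
        else "maturation probability g0/(b+g0)"
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$axis_value, r$evolved_beta_ratio, type = "b", pch = 16,
                 xlab = xl, ylab = expression(beta[J]^"*" / beta[A]),
                 ylim = c(1, x$params$d), main = "Evolved juvenile susceptibility")
  graphics::plot(r$axis_value, r$evolved_prevalence, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = xl, ylab = "prevalence")
  graphics::lines(r$axis_value, r$initial_prevalence, type = "b", pch = 1,
                  col = "grey50")
  graphics::legend("topleft", c("evolved", "initial"), pch = c(16, 1),
                   col = c("black", "grey50"), bty = "n")
  graphics::plot(r$axis_value, r$evolved_juvenile_fraction, type = "b",
                 pch = 16, ylim = c(0, 1), xlab = xl,
                 ylab = "juvenile fraction")
  graphics::lines(r$axis_value, r$initial_juvenile_fraction, type = "b",
                  pch = 1, col = "grey50")
  invisible(x)
}
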