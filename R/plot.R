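#' Plot a simulated trajectory
#'
#' Path in the participant frame, start marked with a circle, goal with a
#' cross.
#'
#' @param x a `pp_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pp_trajectory <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x (m)",
                 ylab = "y (m)",
                 main = sprintf("%s movement", attr(x, "movement_class")),
                 ...)
  graphics::points(x$x[1], x$y[1], pch = 1)
  g <- attr(x, "goal")
  graphics::points(g[1], g[2], pch = 4)
  invisible(x)
}

#' Plot session pass-rate curves
#'
#' Percent passes per target location for each order condition, the
#' standard hysteresis picture: the ascending curve rises at a larger
#' target distance than the descending curve.
#'
#' @param x a `pp_session`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pp_session <- function(x, ...) {
  conds <- intersect(c("ascending", "descending", "random"),
                     unique(x$trials$order_condition))
  cols <- c(ascending = "red", descending = "blue", random = "black")
  ltys <- c(ascending = 2, descending = 1, random = 3)
  graphics::plot(NA, xlim = range(x$model$space$targets[, 2]),
                 ylim = c(0, 100), xlab = "target y (m)",
                 ylab = "% passes", main = "Pass rate by target", ...)
  for (cc in conds) {
    pr <- pass_rate_by_target(x, cc)
    graphics::lines(pr$target_y, 100 * pr$rate, col = cols[[cc]],
                    lty = ltys[[cc]])
  }
  graphics::legend("topleft", legend = conds, col = cols[conds],
                   lty = ltys[conds], bty = "n")
  invisible(x)
}

#' Plot the decision potential landscape
#'
#' Potential V(x) for a set of alpha values, illustrating the saddle-node
#' bifurcation: for |alpha| < alpha_c two wells coexist; beyond, one well
#' remains.
#'
#' @param x a `pp_model`.
#' @param alphas control-parameter values to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pp_model <- function(x, alphas = c(-0.5, -0.2, 0, 0.2, 0.5), ...) {
  xx <- seq(-1.8, 1.8, length.out = 301)
  V <- sapply(alphas, function(a) decision_potential(xx, a))
  graphics::matplot(xx, V, type = "l", lty = 1, xlab = "decision state x",
                    ylab = "V(x)", main = "Action-selection potential", ...)
  graphics::legend("top", legend = sprintf("alpha = %.2f", alphas),
                   col = seq_along(alphas), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
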