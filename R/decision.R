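#' Decision-dynamics parameters
#'
#' The pass/no-pass decision is governed by the normal-form bistable system
#' \eqn{\dot x = -\alpha + x - x^3}, driven by the re-normalised E/A ratio
#' \eqn{\alpha = (\sigma - E/A)\,\delta}. `sigma` is the E/A value at the
#' centre of the bistable band (where \eqn{\alpha = 0}); `delta` scales E/A
#' units onto \eqn{\alpha} units and thereby sets the hysteresis width
#' \eqn{2\alpha_c/\delta} in E/A units.
#'
#' Defaults are calibrated from the empirical transition points: `sigma` =
#' 0.825 (midpoint of the ascending/descending transitions 0.853 and 0.797)
#' and `delta` = alpha_c / 0.028, which maps the saddle-node boundaries of
#' the bistable band exactly onto those two values.
#'
#' @param sigma transition-centre E/A (dimensionless).
#' @param delta E/A-to-alpha scaling (> 0).
#' @param affordance_distance_mode how the trial E/A is computed:
#'   `"target_y_over_reach"` (empirical definition; default) or
#'   `"euclidean_hand_target"` (hand-to-target distance at decision time).
#' @return Object of class `pp_decision`.
#' @export
decision_params <- function(sigma = 0.825, delta = critical_alpha() / 0.028,
                            affordance_distance_mode =
                              c("target_y_over_reach", "euclidean_hand_target")) {
  affordance_distance_mode <- match.arg(affordance_distance_mode)
  stopifnot(delta > 0, is.finite(sigma))
  structure(list(sigma = sigma, delta = delta,
                 affordance_distance_mode = affordance_distance_mode),
            class = "pp_decision")
}

#' Map an E/A ratio onto the decision control parameter
#'
#' \eqn{\alpha = (\sigma - E/A)\,\delta}. Near targets (small E/A) give
#' \eqn{\alpha > 0} (the no-pass branch is the only attractor); far targets
#' give \eqn{\alpha < 0} (pass).
#'
#' @param ea E/A ratio (>= 0); vectorised.
#' @param p a [decision_params()] object.
#' @return alpha (dimensionless).
#' @export
compute_alpha <- function(ea, p = decision_params()) {
  if (any(ea < 0)) stop("ea must be non-negative")
  (p$sigma - ea) * p$delta
}

#' Decision flow field
#'
#' Right-hand side \eqn{\dot x = -\alpha + x - x^3}; vectorised in `x`.
#'
#' @param x decision state.
#' @param alpha control parameter.
#' @return dx/dt.
#' @export
decision_flow <- function(x, alpha) -alpha + x - x^3

#' Decision potential
#'
#' Potential \eqn{V(x) = \alpha x - x^2/2 + x^4/4}, so that
#' \eqn{\dot x = -V'(x)} reproduces the flow field exactly.
#'
#' @inheritParams decision_flow
#' @return V(x).
#' @export
decision_potential <- function(x, alpha) alpha * x - x^2 / 2 + x^4 / 4

#' Fixed points of the decision dynamics
#'
#' Real roots of \eqn{x - x^3 = \alpha} with stability labels. A root x* is
#' stable iff the linearisation \eqn{1 - 3x^2} is negative there.
#'
#' @param alpha control parameter (scalar).
#' @return A data frame with columns `x` (sorted ascending) and `stable`.
#' @examples
#' fixed_points(0)    # -1 (stable), 0 (unstable), +1 (stable)
#' fixed_points(0.5)  # single stable root near -1.19
#' @export
fixed_points <- function(alpha) {
  stopifnot(length(alpha) == 1, is.finite(alpha))
  # -x^3 + x - alpha = 0; polyroot takes ascending coefficients
  r <- polyroot(c(-alpha, 1, 0, -1))
  re <- Re(r)[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))]
  # one Newton polish where the derivative is safely nonzero
  fp <- 1 - 3 * re^2
  ok <- abs(fp) > 1e-6
  re[ok] <- re[ok] - (re[ok] - re[ok]^3 - alpha) / fp[ok]
  re <- sort(re)
  if (length(re) > 1) re <- re[c(TRUE, diff(re) > 1e-7)]
  data.frame(x = re, stable = 1 - 3 * re^2 < 0)
}

#' Saddle-node critical value of the control parameter
#'
#' The bistable band is \eqn{|\alpha| < \alpha_c} with
#' \eqn{\alpha_c = 2/(3\sqrt 3) \approx 0.3849}: the value at which
#' \eqn{x - x^3 = \alpha} and \eqn{1 - 3x^2 = 0} hold simultaneously and a
#' stable/unstable pair annihilates.
#'
#' @return alpha_c (dimensionless).
#' @export
critical_alpha <- function() 2 / (3 * sqrt(3))

#' Integrate one pass/no-pass decision
#'
#' Integrates the decision flow from `x0` for `n_steps` fixed-size RK4 steps
#' and reads the mode off the sign of the end state: the positive stable
#' branch codes *pass*, the negative branch *no pass*. The end state is
#' returned for trial-to-trial carryover (hysteresis memory). If the end
#' state has not left the neighbourhood of zero (unresolved), the previous
#' mode is retained; with no previous mode the conservative default is
#' no-pass.
#'
#' @param x0 initial decision state.
#' @param alpha control parameter for this trial.
#' @param n_steps number of integration steps (default 1500).
#' @param dt step size (default 0.005).
#' @param last_mode previous trial's mode (`"pass"`, `"no_pass"` or `NA`).
#' @param eps resolution threshold on |x_end|.
#' @return List with `mode` and `x` (end state).
#' @export
decide <- function(x0, alpha, n_steps = 1500, dt = 0.005, last_mode = NA,
                   eps = 1e-3) {
  stopifnot(n_steps >= 1, dt > 0)
  x <- x0
  h2 <- dt / 2
  for (i in seq_len(n_steps)) {
    k1 <- -alpha + x - x^3
    x2 <- x + h2 * k1
    k2 <- -alpha + x2 - x2^3
    x3 <- x + h2 * k2
    k3 <- -alpha + x3 - x3^3
    x4 <- x + dt * k3
    k4 <- -alpha + x4 - x4^3
    x <- x + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  mode <- if (abs(x) < eps) {
    if (is.na(last_mode)) "no_pass" else last_mode
  } else if (x > 0) "pass" else "no_pass"
  list(mode = mode, x = x)
}

#' Hysteresis sweep over a sequence of E/A values
#'
#' Runs [decide()] along a strictly monotone E/A sequence with state
#' carryover and returns the E/A at which the mode first flips (midpoint of
#' the two flanking grid values). On an ascending sweep the no-pass-to-pass
#' flip occurs just past \eqn{\sigma + \alpha_c/\delta}; descending, just
#' past \eqn{\sigma - \alpha_c/\delta}.
#'
#' @param ea_values strictly monotone numeric vector (length >= 3).
#' @param p a [decision_params()].
#' @param x0 initial decision state (default 0).
#' @param ... further arguments to [decide()].
#' @return List with `transition_ea` (`NA` if no flip occurs in range),
#'   `direction` (`"ascending"`/`"descending"`), `modes` (per-grid-point
#'   modes) and `x_end`.
#' @examples
#' p <- decision_params()
#' sweep_hysteresis(seq(0.5, 1.1, by = 0.004), p)$transition_ea   # ~0.853
#' sweep_hysteresis(seq(1.1, 0.5, by = -0.004), p)$transition_ea  # ~0.797
#' @export
sweep_hysteresis <- function(ea_values, p = decision_params(), x0 = 0, ...) {
  stopifnot(length(ea_values) >= 3)
  d <- diff(ea_values)
  if (!(all(d > 0) || all(d < 0)))
    stop("ea_values must be strictly monotone")
  direction <- if (d[1] > 0) "ascending" else "descending"
  x <- x0
  last <- NA
  modes <- character(length(ea_values))
  for (i in seq_along(ea_values)) {
    r <- decide(x, compute_alpha(ea_values[i], p), last_mode = last, ...)
    modes[i] <- r$mode
    x <- r$x
    last <- r$mode
  }
  flip <- which(modes[-1] != modes[-length(modes)])
  transition <- if (length(flip) == 0) NA_real_ else
    (ea_values[flip[1]] + ea_values[flip[1] + 1]) / 2
  list(transition_ea = transition, direction = direction, modes = modes,
       x_end = x)
}

#' Bifurcation table of the decision dynamics
#'
#' Tabulates the fixed points and their stability over a grid of alpha
#' values, bracketing the saddle-node boundaries.
#'
#' @param alpha_values numeric vector of control-parameter values.
#' @return Data frame with columns `alpha`, `x`, `stable`, `n_roots`.
#' @export
bifurcation_table <- function(alpha_values = seq(-0.6, 0.6, by = 0.02)) {
  out <- lapply(alpha_values, function(a) {
    fp <- fixed_points(a)
    data.frame(alpha = a, x = fp$x, stable = fp$stable, n_roots = nrow(fp))
  })
  do.call(rbind, out)
}
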