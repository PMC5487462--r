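#' Construct a pick-and-place behavioral-dynamics model
#'
#' Bundles the task geometry, steering and velocity dynamics, decision
#' dynamics, initial-angle model, pass jitter and integration settings into
#' a single model object. Sessions are generated with
#' [simulate.pp_model()] / [run_session()] and analysed with the
#' measurement operators ([pass_rate_by_target()], [transition_point()],
#' [curvature_area()], ...).
#'
#' @param space a [task_space()].
#' @param steering a [steering_params()].
#' @param velocity a [velocity_params()].
#' @param decision a [decision_params()].
#' @param angles an [initial_angle_model()].
#' @param jitter a [pass_jitter()].
#' @param pass_strategy which tabletop pass anchor the agent uses:
#'   `"near_confederate"` or `"near_target"`.
#' @param dt Euler step of the movement integration (s).
#' @param stop_radius arrival radius (m).
#' @param max_steps movement step budget.
#' @param heading_noise_deg per-step uniform heading-noise half-width (deg).
#' @param decision_steps,decision_dt RK4 schedule of the per-trial decision
#'   integration.
#' @param carry_across_blocks logical; carry the decision state across block
#'   boundaries (default `TRUE`; the state resets to 0 only at session
#'   start).
#' @return Object of class `pp_model`.
#' @examples
#' m <- pp_model()
#' m
#' @export
pp_model <- function(space = task_space(),
                     steering = steering_params(),
                     velocity = velocity_params(),
                     decision = decision_params(),
                     angles = initial_angle_model(),
                     jitter = pass_jitter(),
                     pass_strategy = c("near_confederate", "near_target"),
                     dt = 0.01, stop_radius = 0.04, max_steps = 5000,
                     heading_noise_deg = 1.14,
                     decision_steps = 1500, decision_dt = 0.005,
                     carry_across_blocks = TRUE) {
  pass_strategy <- match.arg(pass_strategy)
  stopifnot(inherits(space, "pp_task_space"), inherits(steering, "pp_steering"),
            inherits(velocity, "pp_velocity"), inherits(decision, "pp_decision"),
            inherits(angles, "pp_angles"), inherits(jitter, "pp_jitter"),
            dt > 0, stop_radius > 0, max_steps > 0, heading_noise_deg >= 0,
            decision_steps >= 1, decision_dt > 0)
  structure(list(space = space, steering = steering, velocity = velocity,
                 decision = decision, angles = angles, jitter = jitter,
                 pass_strategy = pass_strategy,
                 integration = list(dt = dt, stop_radius = stop_radius,
                                    max_steps = max_steps,
                                    heading_noise = heading_noise_deg * pi / 180,
                                    decision_steps = decision_steps,
                                    decision_dt = decision_dt),
                 carry_across_blocks = carry_across_blocks),
            class = "pp_model")
}

#' @export
print.pp_model <- function(x, ...) {
  cat("Pick-and-place behavioral-dynamics model\n")
  cat(sprintf("  reach R_A = %.3f m; pass strategy: %s\n",
              x$space$reach, x$pass_strategy))
  cat(sprintf("  steering: b_g = %.3g, k_g = %.3g, c1 = %.2g, c2 = %.2g\n",
              x$steering$b_g, x$steering$k_g, x$steering$c1, x$steering$c2))
  cat(sprintf("  velocity: b_v = %.3g, k_v = %.3g, C_v = %.3g/%.3g/%.3g m/s (pickup/pass/target)\n",
              x$velocity$b_v, x$velocity$k_v, x$velocity$C_v[["pickup"]],
              x$velocity$C_v[["pass"]], x$velocity$C_v[["target"]]))
  cat(sprintf("  decision: sigma = %.4g, delta = %.4g (band %.3f..%.3f E/A), mode: %s\n",
              x$decision$sigma, x$decision$delta,
              x$decision$sigma - critical_alpha() / x$decision$delta,
              x$decision$sigma + critical_alpha() / x$decision$delta,
              x$decision$affordance_distance_mode))
  cat(sprintf("  integration: dt = %.3g s, stop radius = %.2g m, heading noise +/- %.3g deg\n",
              x$integration$dt, x$integration$stop_radius,
              x$integration$heading_noise * 180 / pi))
  invisible(x)
}

#' @export
summary.pp_model <- function(object, ...) {
  print(object)
  band <- critical_alpha() / object$decision$delta
  cat("\nAnalytic decision structure:\n")
  cat(sprintf("  critical alpha: %.4f; hysteresis width: %.4f E/A\n",
              critical_alpha(), 2 * band))
  cat(sprintf("  ascending transition (band edge): %.4f E/A\n",
              object$decision$sigma + band))
  cat(sprintf("  descending transition (band edge): %.4f E/A\n",
              object$decision$sigma - band))
  invisible(object)
}
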