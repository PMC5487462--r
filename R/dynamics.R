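#' Steering (heading) dynamics parameters
#'
#' Parameters of the damped angular spring that accelerates the
#' end-effector's heading toward the goal direction:
#' \deqn{\ddot\varphi = -b_g\,\dot\varphi - k_g\,(\varphi - \theta_g)\,
#'   (e^{-c_1 d_g} + c_2)}
#' The stiffness is modulated by goal distance \eqn{d_g}: the spring hardens
#' as the goal is approached (the exponential term), with floor `c2` so the
#' restoring torque never vanishes at large distance.
#'
#' Defaults are scaled to sub-second hand movements: the loop is overdamped
#' for every goal distance (\eqn{b_g^2 > 4 k_g (1 + c_2)}), so the heading
#' error decays without ringing.
#'
#' @param b_g angular damping (1/s).
#' @param k_g angular stiffness (1/s^2).
#' @param c1 distance decay rate of the stiffness modulation (1/m).
#' @param c2 dimensionless stiffness offset.
#' @return Object of class `pp_steering`.
#' @export
steering_params <- function(b_g = 20, k_g = 60, c1 = 0.4, c2 = 0.4) {
  stopifnot(b_g > 0, k_g > 0, c1 > 0, c2 > 0)
  structure(list(b_g = b_g, k_g = k_g, c1 = c1, c2 = c2),
            class = "pp_steering")
}

#' Velocity dynamics parameters
#'
#' Parameters of the second-order non-constant speed law
#' \deqn{\ddot v = -b_v\,\dot v - k_v\,(v - C_v (1 - e^{-d_g}))}
#' The quasi-static speed target \eqn{C_v (1 - e^{-d_g})} rises toward the
#' maximum-speed constant `C_v` when the goal is far and collapses to zero on
#' approach, producing the single-peaked bell-like profile of natural
#' reaches. `C_v` may differ per movement class (pickup / pass / target
#' transport) because the three classes span different distances but similar
#' peak speeds; defaults are calibrated with [calibrate_speed()] so that mean
#' simulated peak speeds match the empirical 1.46 / 1.75 / 1.80 m/s.
#'
#' @param b_v speed damping (1/s).
#' @param k_v speed stiffness (1/s^2). The default pair (60, 900) is
#'   critically damped with poles at -30 1/s.
#' @param C_v maximum-speed constant (m/s); either a single value or a named
#'   vector/list with entries `pickup`, `pass`, `target`.
#' @return Object of class `pp_velocity`.
#' @export
velocity_params <- function(b_v = 60, k_v = 900,
                            C_v = c(pickup = 5.41, pass = 4.94, target = 2.53)) {
  stopifnot(b_v > 0, k_v > 0, all(unlist(C_v) > 0))
  C_v <- unlist(C_v)
  if (length(C_v) == 1 && is.null(names(C_v)))
    C_v <- c(pickup = C_v, pass = C_v, target = C_v)
  stopifnot(all(c("pickup", "pass", "target") %in% names(C_v)))
  structure(list(b_v = b_v, k_v = k_v, C_v = C_v), class = "pp_velocity")
}

.wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Goal distance and signed goal angle
#'
#' Distance and direction of the goal from the current end-effector
#' position. The heading convention follows the equations of motion
#' (\eqn{\dot x = v \sin\varphi}, \eqn{\dot y = v \cos\varphi}): angles are
#' measured from the +y axis, positive toward +x, so the goal angle is the
#' signed two-argument angle `atan2(dx, dy)` in (-pi, pi]. Its magnitude
#' equals the unsigned arccos form \eqn{\theta_g = \cos^{-1}[(Y_g - y)/d_g]};
#' the sign distinguishes goals to the left/right of straight-ahead so the
#' restoring torque can steer both ways.
#'
#' @param pos numeric length-2 current position (m).
#' @param goal numeric length-2 goal position (m).
#' @return List with `distance` (m) and `goal_angle` (rad).
#' @examples
#' goal_geometry(c(0, 0), c(3, 4))  # distance 5, angle atan2(3, 4)
#' @export
goal_geometry <- function(pos, goal) {
  stopifnot(length(pos) == 2, length(goal) == 2,
            all(is.finite(pos)), all(is.finite(goal)))
  dx <- goal[1] - pos[1]
  dy <- goal[2] - pos[2]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("degenerate geometry: position coincides with goal")
  list(distance = d, goal_angle = atan2(dx, dy))
}

#' Heading angular acceleration
#'
#' Evaluates the steering law for a heading/heading-rate pair against a goal
#' geometry. The error \eqn{\varphi - \theta_g} is wrapped to (-pi, pi]
#' before the spring term to avoid 2*pi discontinuities.
#'
#' @param heading heading angle (rad, from +y toward +x).
#' @param heading_rate heading rate (rad/s).
#' @param geom a [goal_geometry()] result (fields `distance`, `goal_angle`).
#' @param p a [steering_params()] object.
#' @return Angular acceleration (rad/s^2).
#' @export
steering_accel <- function(heading, heading_rate, geom, p = steering_params()) {
  err <- .wrap_angle(heading - geom$goal_angle)
  -p$b_g * heading_rate - p$k_g * err * (exp(-p$c1 * geom$distance) + p$c2)
}

#' Speed acceleration
#'
#' Evaluates the second-order velocity law at the current speed, speed rate
#' and goal distance. `d_g` enters nondimensionalised by a 1 m reference
#' length.
#'
#' @param speed current speed (m/s).
#' @param speed_rate current speed rate (m/s^2).
#' @param d_g goal distance (m, >= 0).
#' @param p a [velocity_params()] object.
#' @param C_v maximum-speed constant to use (m/s); defaults to the `target`
#'   entry of `p$C_v`.
#' @return Speed acceleration (m/s^2).
#' @export
velocity_accel <- function(speed, speed_rate, d_g, p = velocity_params(),
                           C_v = p$C_v[["target"]]) {
  if (d_g < 0) stop("d_g must be non-negative")
  -p$b_v * speed_rate - p$k_v * (speed - C_v * (1 - exp(-d_g)))
}

#' One explicit-Euler step of the six-dimensional movement system
#'
#' Advances position, heading, heading rate, speed and speed rate by one
#' Euler step of size `dt`, then adds uniform heading noise in
#' `[-heading_noise, +heading_noise]` and clamps speed at zero from below
#' (the second-order law can transiently drive it negative near the goal).
#'
#' @param state list with `pos` (length-2), `heading`, `heading_rate`,
#'   `speed`, `speed_rate`.
#' @param goal numeric length-2 goal (m).
#' @param steering a [steering_params()].
#' @param velocity a [velocity_params()].
#' @param dt time step (s, > 0).
#' @param heading_noise half-width of the per-step uniform heading noise
#'   (rad); 0 disables noise. Draws use R's global RNG.
#' @param C_v maximum-speed constant for this movement (m/s).
#' @return The updated state list.
#' @export
step_state <- function(state, goal, steering = steering_params(),
                       velocity = velocity_params(), dt = 0.01,
                       heading_noise = 0, C_v = velocity$C_v[["target"]]) {
  stopifnot(dt > 0)
  g <- goal_geometry(state$pos, goal)
  dphi <- steering_accel(state$heading, state$heading_rate, g, steering)
  dv <- velocity_accel(state$speed, state$speed_rate, g$distance, velocity, C_v)
  new <- state
  new$pos <- state$pos + dt * state$speed * c(sin(state$heading), cos(state$heading))
  new$heading <- state$heading + dt * state$heading_rate
  new$heading_rate <- state$heading_rate + dt * dphi
  new$speed <- max(0, state$speed + dt * state$speed_rate)
  new$speed_rate <- state$speed_rate + dt * dv
  if (heading_noise > 0)
    new$heading <- new$heading + stats::runif(1, -heading_noise, heading_noise)
  if (!all(is.finite(c(new$pos, new$heading, new$heading_rate, new$speed,
                       new$speed_rate))))
    stop("integration diverged: non-finite state")
  new
}

#' Integrate a single goal-directed movement
#'
#' Runs the Euler scheme of [step_state()] from a start position and initial
#' heading until the end-effector is within `stop_radius` of the goal or
#' `max_steps` is exhausted. Movements start from rest (zero heading rate,
#' speed and speed rate).
#'
#' @param start numeric length-2 start position (m, participant frame).
#' @param heading0 initial heading (rad, model convention).
#' @param goal numeric length-2 goal position (m).
#' @param steering,velocity parameter objects.
#' @param movement_class `"pickup"`, `"pass"` or `"target"`; selects the
#'   `C_v` entry and is recorded on the trajectory.
#' @param dt Euler step (s), default 0.01.
#' @param stop_radius arrival radius (m), default 0.04.
#' @param max_steps maximum number of steps, default 5000 (50 model-seconds).
#' @param heading_noise per-step uniform heading-noise half-width (rad);
#'   default the empirical-protocol 1.14 degrees.
#' @return Object of class `pp_trajectory`: a data frame with columns `t`,
#'   `x`, `y`, `heading`, `speed`, and attributes `arrived` (logical),
#'   `movement_class`, `goal`.
#' @examples
#' tr <- integrate_movement(c(0, 0), heading0 = atan2(1, 0), goal = c(1, 0),
#'                          heading_noise = 0)
#' attr(tr, "arrived")
#' @export
integrate_movement <- function(start, heading0, goal,
                               steering = steering_params(),
                               velocity = velocity_params(),
                               movement_class = c("target", "pickup", "pass"),
                               dt = 0.01, stop_radius = 0.04, max_steps = 5000,
                               heading_noise = 1.14 * pi / 180) {
  movement_class <- match.arg(movement_class)
  stopifnot(max_steps > 0, dt > 0, stop_radius > 0)
  dx0 <- goal[1] - start[1]; dy0 <- goal[2] - start[2]
  if (sqrt(dx0^2 + dy0^2) <= stop_radius)
    stop("start position already within stop_radius of goal")

  b_g <- steering$b_g; k_g <- steering$k_g; c1 <- steering$c1; c2 <- steering$c2
  b_v <- velocity$b_v; k_v <- velocity$k_v
  Cv <- velocity$C_v[[movement_class]]
  gx <- goal[1]; gy <- goal[2]

  n <- max_steps + 1L
  X <- numeric(n); Y <- numeric(n); H <- numeric(n); S <- numeric(n)
  x <- start[1]; y <- start[2]
  phi <- heading0; dphi <- 0; v <- 0; dv <- 0
  X[1] <- x; Y[1] <- y; H[1] <- phi; S[1] <- v
  noise <- heading_noise > 0
  if (noise) eps <- stats::runif(max_steps, -heading_noise, heading_noise)
  arrived <- FALSE
  k <- 1L
  while (k <= max_steps) {
    ddx <- gx - x; ddy <- gy - y
    d <- sqrt(ddx^2 + ddy^2)
    theta <- atan2(ddx, ddy)
    err <- phi - theta
    err <- (err + pi) %% (2 * pi) - pi
    if (err == -pi) err <- pi
    a_phi <- -b_g * dphi - k_g * err * (exp(-c1 * d) + c2)
    a_v <- -b_v * dv - k_v * (v - Cv * (1 - exp(-d)))
    x <- x + dt * v * sin(phi)
    y <- y + dt * v * cos(phi)
    phi <- phi + dt * dphi
    dphi <- dphi + dt * a_phi
    v <- v + dt * dv
    if (v < 0) v <- 0
    dv <- dv + dt * a_v
    if (noise) phi <- phi + eps[k]
    k <- k + 1L
    X[k] <- x; Y[k] <- y; H[k] <- phi; S[k] <- v
    if (sqrt((gx - x)^2 + (gy - y)^2) <= stop_radius) { arrived <- TRUE; break }
  }
  if (!is.finite(x) || !is.finite(y) || !is.finite(phi) || !is.finite(v))
    stop("integration diverged: non-finite state")
  idx <- seq_len(k)
  out <- data.frame(t = (idx - 1L) * dt, x = X[idx], y = Y[idx],
                    heading = H[idx], speed = S[idx])
  attr(out, "arrived") <- arrived
  attr(out, "movement_class") <- movement_class
  attr(out, "goal") <- c(gx, gy)
  class(out) <- c("pp_trajectory", "data.frame")
  out
}
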