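#' Initial-movement-angle model
#'
#' Each sub-task movement starts with a stereotyped initial heading that
#' depends only on the action-scaled pickup location label (0.2..1.0), not
#' on the movement's end point. Angles are specified in the *printed
#' analysis convention*: degrees counter-clockwise from the table's +x axis
#' in a frame whose y axis points toward the participant (see
#' [heading_to_printed_angle()]). Pickup movements interpolate linearly
#' between the endpoints measured at the nearest and farthest pickup;
#' pass and target movements interpolate with a saturating exponential whose
#' increments shrink as pickup distance grows.
#'
#' @param pickup_endpoints angles (deg) at the nearest and farthest pickup
#'   for pickup movements.
#' @param pass_endpoints,target_endpoints same for pass and target
#'   transport movements.
#' @param rate saturation rate of the exponential interpolation (> 0).
#' @param noise_halfwidth half-width of the uniform noise added to the mean
#'   initial angle (deg, >= 0).
#' @return Object of class `pp_angles`.
#' @export
initial_angle_model <- function(pickup_endpoints = c(185.88, 201.59),
                                pass_endpoints = c(31.21, -35.15),
                                target_endpoints = c(31.35, -33.89),
                                rate = 3, noise_halfwidth = 20) {
  stopifnot(length(pickup_endpoints) == 2, length(pass_endpoints) == 2,
            length(target_endpoints) == 2, rate > 0, noise_halfwidth >= 0)
  structure(list(pickup_endpoints = pickup_endpoints,
                 pass_endpoints = pass_endpoints,
                 target_endpoints = target_endpoints,
                 rate = rate, noise_halfwidth = noise_halfwidth),
            class = "pp_angles")
}

#' Mean initial angle (printed convention) for a movement class and pickup
#'
#' @param movement_class `"pickup"`, `"pass"` or `"target"`.
#' @param pickup_index pickup location index 1..5 (1 = nearest).
#' @param model an [initial_angle_model()].
#' @return Mean initial angle in degrees, printed analysis convention.
#' @export
mean_initial_angle <- function(movement_class = c("pickup", "pass", "target"),
                               pickup_index, model = initial_angle_model()) {
  movement_class <- match.arg(movement_class)
  if (any(pickup_index < 1 | pickup_index > 5))
    stop("pickup_index must be in 1..5")
  u <- (pickup_index - 1) / 4  # 0 at nearest, 1 at farthest
  if (movement_class == "pickup") {
    e <- model$pickup_endpoints
    e[1] + u * (e[2] - e[1])
  } else {
    e <- if (movement_class == "pass") model$pass_endpoints else
      model$target_endpoints
    r <- model$rate
    w <- (1 - exp(-r * u)) / (1 - exp(-r))  # 0 at u=0, 1 at u=1, saturating
    e[1] + w * (e[2] - e[1])
  }
}

#' Convert between model headings and printed analysis angles
#'
#' The equations of motion measure the heading \eqn{\varphi} from the
#' participant frame's +y axis (pointing away from the participant) toward
#' +x. The printed analysis angles are measured counter-clockwise from +x
#' in a frame whose y axis is inverted (pointing toward the participant) —
#' the convention under which left-to-right movements are 0 degrees,
#' right-to-left 180 degrees, and the straight-line angle to the pickups
#' *increases* with pickup distance. The conversion is
#' `printed = heading_deg - 90` (wrapped to (-180, 180]).
#'
#' @param heading heading in radians (model convention).
#' @return Printed-convention angle in degrees.
#' @export
heading_to_printed_angle <- function(heading) {
  a <- heading * 180 / pi - 90
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' @rdname heading_to_printed_angle
#' @param angle printed-convention angle in degrees.
#' @return Heading in radians (model convention), wrapped to (-pi, pi].
#' @export
printed_angle_to_heading <- function(angle) {
  .wrap_angle((angle + 90) * pi / 180)
}

#' Draw the initial heading for a movement
#'
#' Mean angle from [mean_initial_angle()] plus uniform noise of half-width
#' `model$noise_halfwidth` degrees, converted to the model heading
#' convention. Uses R's global RNG.
#'
#' @inheritParams mean_initial_angle
#' @param noise logical; add the uniform noise term (default `TRUE`).
#' @return Heading in radians (model convention).
#' @export
initial_heading <- function(movement_class, pickup_index,
                            model = initial_angle_model(), noise = TRUE) {
  a <- mean_initial_angle(movement_class, pickup_index, model)
  if (noise && model$noise_halfwidth > 0)
    a <- a + stats::runif(length(a), -model$noise_halfwidth,
                          model$noise_halfwidth)
  printed_angle_to_heading(a)
}

#' Pass-location jitter model
#'
#' Trial-to-trial variability of the pass/release point: a radial offset
#' drawn from a lognormal distribution, in a direction uniform on
#' [0, 2*pi), added to the session's pass anchor and clipped to the table.
#'
#' @param meanlog,sdlog lognormal parameters of the radial offset (m).
#'   Defaults give a median offset of 5 cm.
#' @return Object of class `pp_jitter`.
#' @export
pass_jitter <- function(meanlog = log(0.05), sdlog = 0.5) {
  stopifnot(sdlog >= 0)
  structure(list(meanlog = meanlog, sdlog = sdlog), class = "pp_jitter")
}

#' Sample a jittered pass location
#'
#' @param anchor numeric length-2 pass anchor in the *table frame* (m).
#' @param jitter a [pass_jitter()].
#' @param frame a [frame_config()]; the result is clipped to its table.
#' @return Length-2 point in the table frame.
#' @export
sample_pass_location <- function(anchor, jitter = pass_jitter(),
                                 frame = frame_config()) {
  stopifnot(length(anchor) == 2)
  if (any(anchor < 0) || any(anchor > frame$table_size))
    stop("anchor must lie within the table")
  r <- stats::rlnorm(1, jitter$meanlog, jitter$sdlog)
  th <- stats::runif(1, 0, 2 * pi)
  p <- anchor + r * c(cos(th), sin(th))
  pmin(pmax(p, c(0, 0)), frame$table_size)
}
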