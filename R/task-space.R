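#' Table and coordinate-frame configuration
#'
#' The task lives on a rectangular tabletop. Two planar frames are used:
#' the *table frame*, with origin at one table corner and x along the long
#' (1.50 m) edge, and the *participant frame*, with origin at the
#' participant's ready/start hand location, x increasing toward the target
#' side and y increasing away from the participant across the table.
#' `ready_table` places the participant-frame origin inside the table frame.
#'
#' @param ready_table numeric length-2, ready/start location in the table
#'   frame (m). The default is chosen so that all pickup and target grid
#'   points fall inside the table with margin.
#' @param table_size numeric length-2, table extent (m) along x and y.
#' @return An object of class `pp_frame`.
#' @examples
#' fr <- frame_config()
#' to_table_frame(c(0, 0), fr)  # the ready location itself
#' @export
frame_config <- function(ready_table = c(0.35, 0.15),
                         table_size = c(1.50, 0.89)) {
  stopifnot(length(ready_table) == 2, length(table_size) == 2,
            all(is.finite(ready_table)), all(is.finite(table_size)),
            all(table_size > 0))
  if (any(ready_table < 0) || any(ready_table > table_size))
    stop("ready_table must lie within the table bounds")
  structure(list(ready_table = as.numeric(ready_table),
                 table_size = as.numeric(table_size)),
            class = "pp_frame")
}

#' Participant-frame / table-frame conversion
#'
#' Affine translation by the ready location. `to_participant_frame` is the
#' exact inverse of `to_table_frame`.
#'
#' @param p numeric length-2 point, or a 2-column matrix of points.
#' @param frame a [frame_config()] object.
#' @return Point(s) in the other frame, same shape as `p`.
#' @export
to_table_frame <- function(p, frame = frame_config()) {
  stopifnot(inherits(frame, "pp_frame"))
  if (is.matrix(p)) sweep(p, 2, frame$ready_table, "+")
  else as.numeric(p) + frame$ready_table
}

#' @rdname to_table_frame
#' @export
to_participant_frame <- function(p, frame = frame_config()) {
  stopifnot(inherits(frame, "pp_frame"))
  if (is.matrix(p)) sweep(p, 2, frame$ready_table, "-")
  else as.numeric(p) - frame$ready_table
}

# Printed mean pickup y-positions (m, participant frame) and the
# action-scaled labels attached to the five pickup locations.
.pickup_y_printed <- c(-0.014, 0.072, 0.158, 0.244, 0.330)
.pickup_x <- -0.323
.pickup_labels <- c(0.2, 0.4, 0.6, 0.8, 1.0)
.target_x <- 1.037
.target_y <- seq(-0.07, 0.595, by = 0.035)

#' Build the pick-and-place task geometry
#'
#' Five pickup locations on the participant's left (x = -0.323 m) and twenty
#' target locations on the right (x = +1.037 m, y from -0.07 m to 0.595 m in
#' 0.035 m steps), all in the participant frame. Each pickup location carries
#' an action-scaled E/A label in {0.2, 0.4, 0.6, 0.8, 1.0} (fraction of the
#' agent's preferred reach). By default the pickup coordinates are the
#' empirical mean positions; `pickup_mode = "reach_scaled"` instead places
#' pickup y so that the y-distance from a fixed standing offset equals
#' label * reach.
#'
#' Also records the two tabletop pass anchors (table frame): one near the
#' partner's ready hand, one nearer the targets.
#'
#' @param reach preferred comfortable reach distance R_A in metres (> 0).
#' @param frame a [frame_config()].
#' @param pickup_mode `"printed"` (default) or `"reach_scaled"`.
#' @return An object of class `pp_task_space` with elements `reach`,
#'   `pickups` (5x2 matrix), `pickup_labels`, `targets` (20x2 matrix),
#'   `pass_anchor_near_confederate`, `pass_anchor_near_target` (table frame),
#'   and `frame`.
#' @examples
#' ts <- task_space(reach = 0.522)
#' nrow(ts$targets)          # 20
#' diff(ts$targets[, 2])     # 0.035 m spacing
#' @export
task_space <- function(reach = 0.522, frame = frame_config(),
                       pickup_mode = c("printed", "reach_scaled")) {
  pickup_mode <- match.arg(pickup_mode)
  stopifnot(inherits(frame, "pp_frame"))
  if (!is.numeric(reach) || length(reach) != 1 || !is.finite(reach) || reach <= 0)
    stop("reach must be a positive finite number")
  pickup_y <- if (pickup_mode == "printed") .pickup_y_printed else {
    # standing offset fixed so the nearest pickup matches the printed mean
    .pickup_labels * reach - (0.2 * 0.522 + 0.014)
  }
  pickups <- cbind(x = rep(.pickup_x, 5), y = pickup_y)
  targets <- cbind(x = rep(.target_x, 20), y = .target_y)
  grid_tab <- to_table_frame(rbind(pickups, targets), frame)
  if (any(grid_tab < 0) || any(grid_tab[, 1] > frame$table_size[1]) ||
      any(grid_tab[, 2] > frame$table_size[2]))
    stop("task grid points fall outside the table bounds; adjust ready_table")
  structure(list(
    reach = reach,
    pickups = pickups,
    pickup_labels = .pickup_labels,
    targets = targets,
    pass_anchor_near_confederate = c(0.464, 0.5607),
    pass_anchor_near_target = c(0.7695, 0.5893),
    frame = frame,
    pickup_mode = pickup_mode), class = "pp_task_space")
}

#' Environment-to-agent (E/A) ratio
#'
#' The body-scaled control parameter of the pass decision: an environmental
#' distance divided by the agent's preferred reach.
#'
#' @param distance distance in metres (>= 0); vectorised.
#' @param reach preferred reach in metres (> 0).
#' @return `distance / reach` (dimensionless).
#' @examples
#' ea_ratio(0.615, 0.522)  # 1.18
#' ea_ratio(0.896, 0.522)  # 1.72
#' @export
ea_ratio <- function(distance, reach) {
  if (!is.numeric(reach) || length(reach) != 1 || !is.finite(reach) || reach <= 0)
    stop("reach must be a positive finite number")
  if (any(distance < 0)) stop("distance must be non-negative")
  distance / reach
}

#' @export
print.pp_task_space <- function(x, ...) {
  cat("Pick-and-place task space\n")
  cat(sprintf("  reach R_A: %.3f m (pickup coordinates: %s)\n", x$reach, x$pickup_mode))
  cat(sprintf("  5 pickups at x = %.3f m, y in [%.3f, %.3f] m\n",
              x$pickups[1, 1], min(x$pickups[, 2]), max(x$pickups[, 2])))
  cat(sprintf("  20 targets at x = %.3f m, y in [%.3f, %.3f] m (E/A %.2f..%.2f)\n",
              x$targets[1, 1], min(x$targets[, 2]), max(x$targets[, 2]),
              min(x$targets[, 2]) / x$reach, max(x$targets[, 2]) / x$reach))
  invisible(x)
}
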