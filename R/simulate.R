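#' Simulate one trial of the pick-and-place task
#'
#' The trial pipeline: (1) integrate the ready-to-pickup movement; (2)
#' compute the trial E/A ratio from the target (or the hand-to-target
#' distance), map it to the control parameter alpha and integrate the
#' bistable decision with carryover from the previous trial; (3) integrate
#' the transport movement to the jittered pass location (pass) or to the
#' target (no pass).
#'
#' @param model a [pp_model()].
#' @param pickup_index,target_index trial condition (1..5, 1..20).
#' @param decision_x incoming decision state.
#' @param last_mode previous trial's mode (`"pass"`, `"no_pass"` or `NA`).
#' @param movements logical; if `FALSE`, skip movement integration and pass
#'   jitter and produce the decision series only (the default decision mode
#'   does not depend on hand position, so decisions are unchanged).
#' @return List with `decision`, `ea`, `alpha`, `x_end`, `pass_location`
#'   (participant frame; `NULL` unless a pass with movements),
#'   `pickup_trajectory`, `transport_trajectory` (or `NULL`).
#' @export
run_trial <- function(model, pickup_index, target_index, decision_x = 0,
                      last_mode = NA, movements = TRUE) {
  sp <- model$space
  intg <- model$integration
  pickup <- sp$pickups[pickup_index, ]
  target <- sp$targets[target_index, ]

  pickup_traj <- NULL
  if (movements) {
    h0 <- initial_heading("pickup", pickup_index, model$angles)
    pickup_traj <- integrate_movement(c(0, 0), h0, pickup,
                                      model$steering, model$velocity,
                                      movement_class = "pickup",
                                      dt = intg$dt, stop_radius = intg$stop_radius,
                                      max_steps = intg$max_steps,
                                      heading_noise = intg$heading_noise)
  }

  hand <- if (movements) {
    unlist(pickup_traj[nrow(pickup_traj), c("x", "y")], use.names = FALSE)
  } else as.numeric(pickup)
  ea <- switch(model$decision$affordance_distance_mode,
    target_y_over_reach = ea_ratio(max(0, target[["y"]]), sp$reach),
    euclidean_hand_target = ea_ratio(
      sqrt(sum((as.numeric(target) - hand)^2)), sp$reach))
  alpha <- compute_alpha(ea, model$decision)
  dec <- decide(decision_x, alpha, n_steps = intg$decision_steps,
                dt = intg$decision_dt, last_mode = last_mode)

  pass_loc <- NULL
  transport_traj <- NULL
  if (movements) {
    cls <- if (dec$mode == "pass") "pass" else "target"
    h1 <- initial_heading(cls, pickup_index, model$angles)
    goal <- if (dec$mode == "pass") {
      anchor <- if (model$pass_strategy == "near_confederate")
        sp$pass_anchor_near_confederate else sp$pass_anchor_near_target
      tab <- sample_pass_location(anchor, model$jitter, sp$frame)
      pass_loc <- to_participant_frame(tab, sp$frame)
      pass_loc
    } else as.numeric(target)
    transport_traj <- integrate_movement(as.numeric(pickup), h1, goal,
                                         model$steering, model$velocity,
                                         movement_class = cls,
                                         dt = intg$dt,
                                         stop_radius = intg$stop_radius,
                                         max_steps = intg$max_steps,
                                         heading_noise = intg$heading_noise)
  }
  list(decision = dec$mode, ea = ea, alpha = alpha, x_end = dec$x,
       pass_location = pass_loc, pickup_trajectory = pickup_traj,
       transport_trajectory = transport_traj)
}

#' Simulate a full session
#'
#' Runs every trial of a schedule through [run_trial()] with one RNG stream
#' (seeded at session start) and decision-state carryover; the decision
#' state is 0 at trial 1 and, by default, carries across block boundaries.
#'
#' @param model a [pp_model()].
#' @param schedule a [build_schedule()]; defaults to a schedule built from
#'   `seed`.
#' @param seed integer session seed (also the schedule seed when `schedule`
#'   is `NULL`).
#' @param movements logical; integrate hand movements (`TRUE`) or produce
#'   the decision series only (fast; decisions are identical under the
#'   default E/A mode).
#' @return Object of class `pp_session`: list with `trials` (data frame:
#'   schedule columns plus `ea`, `alpha`, `decision`, `x_end`, `pass_x`,
#'   `pass_y`, `arrived_pickup`, `arrived_transport`), `trajectories`
#'   (per-trial list of `pickup`/`transport` trajectories, or `NULL`),
#'   `model`, `seed`, `pass_strategy`.
#' @examples
#' s <- run_session(pp_model(), seed = 1, movements = FALSE)
#' table(s$trials$decision)
#' @export
run_session <- function(model, schedule = NULL, seed = 1L, movements = TRUE) {
  stopifnot(inherits(model, "pp_model"))
  if (is.null(schedule)) schedule <- build_schedule(seed = seed)
  stopifnot(inherits(schedule, "pp_schedule") || is.data.frame(schedule))
  n <- nrow(schedule)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  x <- 0
  last <- NA
  ea <- alpha <- x_end <- pass_x <- pass_y <- rep(NA_real_, n)
  decision <- character(n)
  arr_p <- arr_t <- rep(NA, n)
  trajectories <- if (movements) vector("list", n) else NULL
  prev_block <- schedule$block[1]
  for (i in seq_len(n)) {
    if (!model$carry_across_blocks && schedule$block[i] != prev_block) {
      x <- 0; last <- NA
    }
    prev_block <- schedule$block[i]
    tr <- run_trial(model, schedule$pickup_index[i], schedule$target_index[i],
                    decision_x = x, last_mode = last, movements = movements)
    ea[i] <- tr$ea; alpha[i] <- tr$alpha
    decision[i] <- tr$decision; x_end[i] <- tr$x_end
    if (!is.null(tr$pass_location)) {
      pass_x[i] <- tr$pass_location[1]; pass_y[i] <- tr$pass_location[2]
    }
    if (movements) {
      arr_p[i] <- attr(tr$pickup_trajectory, "arrived")
      arr_t[i] <- attr(tr$transport_trajectory, "arrived")
      trajectories[[i]] <- list(pickup = tr$pickup_trajectory,
                                transport = tr$transport_trajectory)
    }
    x <- tr$x_end
    last <- tr$decision
  }
  trials <- data.frame(as.data.frame(schedule), ea = ea, alpha = alpha,
                       decision = decision, x_end = x_end,
                       pass_x = pass_x, pass_y = pass_y,
                       arrived_pickup = arr_p, arrived_transport = arr_t)
  structure(list(trials = trials, trajectories = trajectories, model = model,
                 seed = as.integer(seed), pass_strategy = model$pass_strategy),
            class = "pp_session")
}

#' @export
print.pp_session <- function(x, ...) {
  n <- nrow(x$trials)
  np <- sum(x$trials$decision == "pass")
  cat(sprintf("Pick-and-place session: %d trials, seed %d, strategy %s\n",
              n, x$seed, x$pass_strategy))
  cat(sprintf("  passes: %d (%.1f%%); movements stored: %s\n", np,
              100 * np / n, !is.null(x$trajectories)))
  invisible(x)
}

#' @export
summary.pp_session <- function(object, ...) {
  print(object)
  tr <- session_transitions(object)
  cat("  transition E/A by condition:\n")
  for (i in seq_len(nrow(tr)))
    cat(sprintf("    %-10s %.4f\n", tr$order_condition[i], tr$transition_ea[i]))
  invisible(object)
}

#' Simulate sessions from a model
#'
#' `stats::simulate()` method: generates `nsim` sessions with seeds
#' `seed, seed + 1, ...`.
#'
#' @param object a [pp_model()].
#' @param nsim number of sessions.
#' @param seed base integer seed.
#' @param movements passed to [run_session()].
#' @param ... unused.
#' @return A list of `pp_session` objects (length `nsim`), or a single
#'   session if `nsim = 1`.
#' @export
simulate.pp_model <- function(object, nsim = 1, seed = 1L, movements = TRUE,
                              ...) {
  sessions <- lapply(seq_len(nsim) - 1L, function(k)
    run_session(object, seed = as.integer(seed) + k, movements = movements))
  if (nsim == 1) sessions[[1]] else sessions
}

#' Run the full simulated experiment
#'
#' Eight sessions by default, half with the near-confederate pass anchor and
#' half with the near-target anchor.
#'
#' @param model a [pp_model()]; its `pass_strategy` is overridden per
#'   session.
#' @param n_sessions number of sessions (>= 1).
#' @param seeds integer vector of session seeds (length `n_sessions`).
#' @param strategies character vector of per-session pass strategies;
#'   default assigns the first half `"near_target"`, the rest
#'   `"near_confederate"`.
#' @param movements passed to [run_session()].
#' @return List of `pp_session` objects.
#' @export
run_experiment <- function(model = pp_model(), n_sessions = 8,
                           seeds = seq_len(n_sessions),
                           strategies = NULL, movements = TRUE) {
  stopifnot(n_sessions >= 1, length(seeds) == n_sessions)
  if (is.null(strategies)) {
    half <- ceiling(n_sessions / 2)
    strategies <- c(rep("near_target", half),
                    rep("near_confederate", n_sessions - half))
  }
  stopifnot(length(strategies) == n_sessions,
            all(strategies %in% c("near_target", "near_confederate")))
  lapply(seq_len(n_sessions), function(i) {
    m <- model
    m$pass_strategy <- strategies[i]
    run_session(m, seed = seeds[i], movements = movements)
  })
}
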