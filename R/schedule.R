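#' Build a 600-trial session schedule
#'
#' Three blocks of 200 trials (5 pickup x 20 target x 2 repetitions per
#' block). In blocks 1 and 3 each pickup location is presented in a run of 40
#' consecutive trials; within a run the 20 targets are swept once in each
#' direction (ascending then descending, or the reverse, per
#' `target_order`). Block 3 reverses block 1's pickup order by default
#' (counterbalancing analogue). In block 2 every (pickup, target) pair
#' appears exactly twice in seeded random order, so that over the session
#' each pair appears exactly six times.
#'
#' @param pickup_order `"ascending"` or `"descending"`: pickup run order in
#'   block 1.
#' @param target_order `"asc-desc"` or `"desc-asc"`: direction of the first
#'   20-trial target sweep within each pickup run.
#' @param seed integer seed for the random block permutation.
#' @param block3_reverses logical; if `TRUE` (default) block 3 presents the
#'   pickup runs in the order opposite to block 1.
#' @return A data frame of class `pp_schedule` with columns `trial_index`,
#'   `block`, `order_condition` (`"ascending"`, `"descending"` or
#'   `"random"`), `pickup_index` (1..5) and `target_index` (1..20), plus
#'   attributes recording the plans and seed.
#' @examples
#' sch <- build_schedule(seed = 1)
#' table(sch$block)                        # 200 200 200
#' table(sch$pickup_index, sch$target_index)[1, 1]  # each pair 6 times
#' @export
build_schedule <- function(pickup_order = c("ascending", "descending"),
                           target_order = c("asc-desc", "desc-asc"),
                           seed = 1L, block3_reverses = TRUE) {
  pickup_order <- match.arg(pickup_order)
  target_order <- match.arg(target_order)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))

  up <- 1:20
  down <- 20:1
  sweep_pair <- if (target_order == "asc-desc") c(up, down) else c(down, up)
  cond_pair <- if (target_order == "asc-desc") {
    rep(c("ascending", "descending"), each = 20)
  } else rep(c("descending", "ascending"), each = 20)

  ordered_block <- function(pickups) {
    data.frame(pickup_index = rep(pickups, each = 40),
               target_index = rep(sweep_pair, times = 5),
               order_condition = rep(cond_pair, times = 5))
  }
  p1 <- if (pickup_order == "ascending") 1:5 else 5:1
  p3 <- if (block3_reverses) rev(p1) else p1
  b1 <- ordered_block(p1)
  b3 <- ordered_block(p3)

  pairs <- expand.grid(pickup_index = 1:5, target_index = 1:20)
  pairs <- rbind(pairs, pairs)
  old <- .Random.seed_exists()
  on.exit(.restore_random_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  b2 <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  b2$order_condition <- "random"

  out <- rbind(cbind(b1, block = 1L), cbind(b2, block = 2L), cbind(b3, block = 3L))
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("trial_index", "block", "order_condition",
                 "pickup_index", "target_index")]
  attr(out, "pickup_order") <- pickup_order
  attr(out, "target_order") <- target_order
  attr(out, "seed") <- as.integer(seed)
  attr(out, "block3_reverses") <- block3_reverses
  class(out) <- c("pp_schedule", "data.frame")
  out
}

# Save/restore the global RNG state so schedule construction does not
# perturb an enclosing simulation stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_random_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Export a schedule with grid coordinates
#'
#' Joins a schedule to a task space, yielding per-trial pickup and target
#' coordinates (metres, participant frame), suitable for CSV export.
#'
#' @param schedule a [build_schedule()] data frame.
#' @param space a [task_space()].
#' @return A data frame with the schedule columns plus `pickup_x`,
#'   `pickup_y`, `target_x`, `target_y`.
#' @export
schedule_coordinates <- function(schedule, space) {
  stopifnot(inherits(schedule, "pp_schedule"), inherits(space, "pp_task_space"))
  data.frame(as.data.frame(schedule),
             pickup_x = space$pickups[schedule$pickup_index, 1],
             pickup_y = space$pickups[schedule$pickup_index, 2],
             target_x = space$targets[schedule$target_index, 1],
             target_y = space$targets[schedule$target_index, 2])
}
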