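#' Write a simulated session to disk
#'
#' Persists a session as three plain-text files in `dir`: `trials.csv` (one
#' row per trial), `trajectories.jsonl` (one JSON record per trajectory
#' sample: `trial`, `movement`, `t`, `x`, `y`, `heading_deg`, `speed`;
#' omitted for decisions-only sessions) and `manifest.json` (schema version,
#' seed, pass strategy and the full parameter snapshot), so a session
#' directory is reproducible from its manifest alone. Numeric columns are
#' written with 17 significant digits, making the round trip through
#' [read_session()] exact.
#'
#' @param session a `pp_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "pp_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trials
  num <- vapply(tr, is.numeric, logical(1))
  out <- tr
  out[num] <- lapply(tr[num], function(v) sprintf("%.17g", v))
  out[num] <- lapply(out[num], function(v) ifelse(v == "nan", NA, v))
  utils::write.csv(out, file.path(dir, "trials.csv"), row.names = FALSE,
                   quote = FALSE, na = "NA")
  if (!is.null(session$trajectories)) {
    con <- file(file.path(dir, "trajectories.jsonl"), "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_along(session$trajectories)) {
      for (mv in names(session$trajectories[[i]])) {
        t_ <- session$trajectories[[i]][[mv]]
        cls <- attr(t_, "movement_class")
        arrived <- attr(t_, "arrived")
        lines <- sprintf(
          '{"trial":%d,"movement":"%s","class":"%s","arrived":%s,"t":%.17g,"x":%.17g,"y":%.17g,"heading_deg":%.17g,"speed":%.17g}',
          i, mv, cls, tolower(as.character(arrived)),
          t_$t, t_$x, t_$y, t_$heading * 180 / pi, t_$speed)
        writeLines(lines, con)
      }
    }
  }
  manifest <- list(schema = "passdyn-session/1", seed = session$seed,
                   pass_strategy = session$pass_strategy,
                   n_trials = nrow(tr),
                   has_trajectories = !is.null(session$trajectories),
                   config = .model_to_config(session$model))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Parameter snapshot of a model in pp_config() shape.
.model_to_config <- function(model) {
  list(
    geometry = list(reach = model$space$reach,
                    ready_table = model$space$frame$ready_table,
                    table_size = model$space$frame$table_size,
                    pickup_mode = model$space$pickup_mode),
    steering = model$steering[c("b_g", "k_g", "c1", "c2")],
    velocity = list(b_v = model$velocity$b_v, k_v = model$velocity$k_v,
                    C_v = as.list(model$velocity$C_v)),
    decision = list(sigma = model$decision$sigma,
                    delta = model$decision$delta,
                    affordance_distance_mode =
                      model$decision$affordance_distance_mode,
                    carry_across_blocks = model$carry_across_blocks),
    angles = unclass(model$angles),
    jitter = unclass(model$jitter),
    integration = list(dt = model$integration$dt,
                       stop_radius = model$integration$stop_radius,
                       max_steps = model$integration$max_steps,
                       heading_noise_deg =
                         model$integration$heading_noise * 180 / pi,
                       decision_steps = model$integration$decision_steps,
                       decision_dt = model$integration$decision_dt),
    pass_strategy = model$pass_strategy)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory containing `manifest.json` and `trials.csv`
#'   (and `trajectories.jsonl` when movements were stored).
#' @return A `pp_session`.
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  tf <- file.path(dir, "trials.csv")
  if (!file.exists(mf)) stop(sprintf("missing manifest.json in %s", dir))
  if (!file.exists(tf)) stop(sprintf("missing trials.csv in %s", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema, "passdyn-session/1"))
    stop("unrecognised session schema")
  trials <- utils::read.csv(tf, stringsAsFactors = FALSE)
  # all-NA numeric columns (e.g. pass coordinates of a pass-free block)
  # parse as logical; restore their numeric type
  for (cc in intersect(c("ea", "alpha", "x_end", "pass_x", "pass_y"),
                       names(trials)))
    trials[[cc]] <- as.numeric(trials[[cc]])
  if (nrow(trials) != manifest$n_trials)
    stop("corrupt session: trials.csv row count disagrees with manifest")
  cfg <- manifest$config
  cfg$seed <- manifest$seed
  model <- as_pp_model(cfg)
  trajectories <- NULL
  if (isTRUE(manifest$has_trajectories)) {
    jf <- file.path(dir, "trajectories.jsonl")
    if (!file.exists(jf)) stop(sprintf("missing trajectories.jsonl in %s", dir))
    rec <- jsonlite::stream_in(file(jf), verbose = FALSE)
    trajectories <- lapply(seq_len(nrow(trials)), function(i) {
      sub <- rec[rec$trial == i, , drop = FALSE]
      out <- lapply(split(sub, sub$movement), function(s) {
        t_ <- data.frame(t = s$t, x = s$x, y = s$y,
                         heading = s$heading_deg * pi / 180, speed = s$speed)
        attr(t_, "arrived") <- s$arrived[1]
        attr(t_, "movement_class") <- s$class[1]
        class(t_) <- c("pp_trajectory", "data.frame")
        t_
      })
      out[intersect(c("pickup", "transport"), names(out))]
    })
  }
  structure(list(trials = trials, trajectories = trajectories, model = model,
                 seed = as.integer(manifest$seed),
                 pass_strategy = manifest$pass_strategy),
            class = "pp_session")
}
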