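#' Default run configuration
#'
#' A fully materialised nested list of every tunable of the simulator, in
#' the shape accepted by [load_config()] and written into session
#' manifests. All lengths are metres, times seconds, angles degrees.
#'
#' @return Named nested list.
#' @export
pp_config <- function() {
  list(
    geometry = list(reach = 0.522, ready_table = c(0.35, 0.15),
                    table_size = c(1.50, 0.89), pickup_mode = "printed"),
    schedule = list(pickup_order = "ascending", target_order = "asc-desc",
                    block3_reverses = TRUE),
    steering = list(b_g = 20, k_g = 60, c1 = 0.4, c2 = 0.4),
    velocity = list(b_v = 60, k_v = 900,
                    C_v = as.list(velocity_params()$C_v)),
    decision = list(sigma = 0.825, delta = critical_alpha() / 0.028,
                    affordance_distance_mode = "target_y_over_reach",
                    carry_across_blocks = TRUE),
    angles = list(pickup_endpoints = c(185.88, 201.59),
                  pass_endpoints = c(31.21, -35.15),
                  target_endpoints = c(31.35, -33.89),
                  rate = 3, noise_halfwidth = 20),
    jitter = list(meanlog = log(0.05), sdlog = 0.5),
    integration = list(dt = 0.01, stop_radius = 0.04, max_steps = 5000,
                       heading_noise_deg = 1.14,
                       decision_steps = 1500, decision_dt = 0.005),
    pass_strategy = "near_confederate",
    seed = 1L)
}

.validate_config <- function(cfg) {
  ref <- pp_config()
  check <- function(given, default, path) {
    extra <- setdiff(names(given), names(default))
    if (length(extra) > 0)
      stop(sprintf("unknown config key: %s",
                   paste0(path, extra, collapse = ", ")))
    for (k in names(given)) {
      if (is.list(default[[k]]) && !is.null(names(default[[k]])) &&
          k != "C_v") {
        if (!is.list(given[[k]]))
          stop(sprintf("config key %s%s must be a mapping", path, k))
        check(given[[k]], default[[k]], paste0(path, k, "."))
      }
    }
  }
  check(cfg, ref, "")
  pos <- c(integration.dt = cfg$integration$dt,
           integration.stop_radius = cfg$integration$stop_radius,
           integration.max_steps = cfg$integration$max_steps,
           integration.decision_dt = cfg$integration$decision_dt,
           integration.decision_steps = cfg$integration$decision_steps,
           geometry.reach = cfg$geometry$reach,
           decision.delta = cfg$decision$delta,
           steering.b_g = cfg$steering$b_g, steering.k_g = cfg$steering$k_g,
           velocity.b_v = cfg$velocity$b_v, velocity.k_v = cfg$velocity$k_v)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad) > 0)
    stop(sprintf("config value must be positive: %s",
                 paste(bad, collapse = ", ")))
  if (cfg$integration$heading_noise_deg < 0)
    stop("config value must be non-negative: integration.heading_noise_deg")
  invisible(cfg)
}

# Recursively overlay user values onto the defaults.
.merge_config <- function(default, given) {
  for (k in names(given)) {
    if (is.list(default[[k]]) && is.list(given[[k]]) &&
        !is.null(names(default[[k]])))
      default[[k]] <- .merge_config(default[[k]], given[[k]])
    else default[[k]] <- given[[k]]
  }
  default
}

#' Load (or save) a run configuration
#'
#' Reads a YAML or JSON configuration, validates it (unknown keys and
#' non-positive integration settings are errors naming the offending key)
#' and fills every unset value with its default, so the returned
#' configuration is self-contained. An empty file yields the full default
#' configuration.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return A validated, fully materialised configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  given <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(given)) given <- list()
  cfg <- .merge_config(pp_config(), given)
  .validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
save_config <- function(cfg, path) {
  .validate_config(.merge_config(pp_config(), cfg))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Instantiate a model from a configuration
#'
#' @param cfg a configuration list as returned by [pp_config()] or
#'   [load_config()].
#' @return A [pp_model()].
#' @export
as_pp_model <- function(cfg = pp_config()) {
  cfg <- .validate_config(.merge_config(pp_config(), cfg))
  pp_model(
    space = task_space(reach = cfg$geometry$reach,
                       frame = frame_config(unlist(cfg$geometry$ready_table),
                                            unlist(cfg$geometry$table_size)),
                       pickup_mode = cfg$geometry$pickup_mode),
    steering = steering_params(cfg$steering$b_g, cfg$steering$k_g,
                               cfg$steering$c1, cfg$steering$c2),
    velocity = velocity_params(cfg$velocity$b_v, cfg$velocity$k_v,
                               unlist(cfg$velocity$C_v)),
    decision = decision_params(cfg$decision$sigma, cfg$decision$delta,
                               cfg$decision$affordance_distance_mode),
    angles = initial_angle_model(unlist(cfg$angles$pickup_endpoints),
                                 unlist(cfg$angles$pass_endpoints),
                                 unlist(cfg$angles$target_endpoints),
                                 cfg$angles$rate, cfg$angles$noise_halfwidth),
    jitter = pass_jitter(cfg$jitter$meanlog, cfg$jitter$sdlog),
    pass_strategy = cfg$pass_strategy,
    dt = cfg$integration$dt, stop_radius = cfg$integration$stop_radius,
    max_steps = cfg$integration$max_steps,
    heading_noise_deg = cfg$integration$heading_noise_deg,
    decision_steps = cfg$integration$decision_steps,
    decision_dt = cfg$integration$decision_dt,
    carry_across_blocks = cfg$decision$carry_across_blocks)
}
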