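#' Time-normalise a trajectory
#'
#' Cubic-spline resample of x(t) and y(t) at `n` uniformly spaced times
#' spanning the recorded interval. Endpoints are preserved exactly.
#'
#' @param traj a trajectory data frame with columns `t`, `x`, `y` (>= 4
#'   samples, strictly increasing `t`).
#' @param n number of output points (default 512).
#' @return A data frame with columns `t`, `x`, `y` of `n` rows; attribute
#'   `movement_class` is carried over if present.
#' @export
time_normalize <- function(traj, n = 512) {
  stopifnot(n >= 2)
  if (nrow(traj) < 4) stop("need at least 4 samples to time-normalize")
  if (any(diff(traj$t) <= 0)) stop("timestamps must be strictly increasing")
  # movements simulated from rest open with a short run of samples at the
  # start position; collapse it to its last sample (the path and endpoints
  # are unchanged) so the spline is fit to the moving portion, as when
  # empirical segments are cut at a boundary crossing
  disp <- cumsum(c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2)))
  i0 <- max(which(disp == 0))
  if (i0 > 1 && nrow(traj) - i0 + 1 >= 4) traj <- traj[i0:nrow(traj), ]
  tt <- seq(traj$t[1], traj$t[nrow(traj)], length.out = n)
  out <- data.frame(
    t = tt,
    x = stats::spline(traj$t, traj$x, xout = tt, method = "fmm")$y,
    y = stats::spline(traj$t, traj$y, xout = tt, method = "fmm")$y)
  attr(out, "movement_class") <- attr(traj, "movement_class")
  out
}

#' Chord-deviation curvature and initial movement angle
#'
#' Quantifies how a movement deviates from the straight line (chord) joining
#' its endpoints. The signed area between path and chord is computed by
#' trapezoidal integration of the perpendicular offset against arc position
#' along the chord; positive area lies to the left of the chord direction
#' (above the chord, for a left-to-right movement). The initial movement
#' angle is the angle between the 1st and 9th points of the time-normalised
#' trajectory, measured counter-clockwise from +x in degrees (left-to-right
#' = 0, right-to-left = 180); the deviation is initial angle minus
#' straight-line (chord) angle.
#'
#' @param nt a time-normalised trajectory (see [time_normalize()]).
#' @return List with `area` (m^2, signed), `initial_angle`,
#'   `straight_line_angle` and `deviation` (degrees).
#' @examples
#' path <- data.frame(t = 0:2, x = c(0, 0.5, 1), y = c(0, 0.2, 0))
#' # triangle above the chord: area +0.1 m^2
#' curvature_area(data.frame(t = seq(0, 2, length = 512),
#'                           x = seq(0, 1, length = 512),
#'                           y = approx(path$x, path$y,
#'                                      seq(0, 1, length = 512))$y))$area
#' @export
curvature_area <- function(nt) {
  n <- nrow(nt)
  if (n < 9) stop("need at least 9 points")
  p0 <- c(nt$x[1], nt$y[1])
  p1 <- c(nt$x[n], nt$y[n])
  chord <- p1 - p0
  L <- sqrt(sum(chord^2))
  if (L == 0) stop("coincident endpoints: chord undefined")
  u <- chord / L
  relx <- nt$x - p0[1]; rely <- nt$y - p0[2]
  s <- relx * u[1] + rely * u[2]          # position along chord
  e <- relx * u[2] * (-1) + rely * u[1]   # signed perpendicular offset (left +)
  area <- pracma::trapz(s, e)
  d9 <- c(nt$x[9] - nt$x[1], nt$y[9] - nt$y[1])
  if (all(d9 == 0)) stop("points 1 and 9 coincide: initial angle undefined")
  ia <- atan2(d9[2], d9[1]) * 180 / pi
  sla <- atan2(chord[2], chord[1]) * 180 / pi
  dev <- ia - sla
  dev <- (dev + 180) %% 360 - 180
  list(area = area, initial_angle = ia, straight_line_angle = sla,
       deviation = dev)
}

#' Time-normalised velocity profile
#'
#' Speeds are computed by finite differences on the raw (non-normalised)
#' samples, then spline-resampled to `n` uniformly spaced times. Returns the
#' profile, its peak, and the normalised time of the peak.
#'
#' @param traj trajectory data frame (`t`, `x`, `y`; >= 4 samples).
#' @param n profile length (default 512).
#' @return List with `profile` (length `n`), `peak` (m/s) and
#'   `peak_fraction` in [0, 1].
#' @export
velocity_profile <- function(traj, n = 512) {
  if (nrow(traj) < 4) stop("need at least 4 samples")
  dt <- diff(traj$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  v <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
  tm <- (traj$t[-1] + traj$t[-nrow(traj)]) / 2
  tt <- seq(tm[1], tm[length(tm)], length.out = n)
  prof <- stats::spline(tm, v, xout = tt, method = "fmm")$y
  pk <- which.max(prof)
  list(profile = prof, peak = prof[pk], peak_fraction = (pk - 1) / (n - 1))
}

#' Per-target pass rates for an order condition
#'
#' Fraction of pass decisions at each of the 20 target locations among
#' trials of the given order condition (ascending / descending sweeps of
#' the ordered blocks, or the random block).
#'
#' @param session a `pp_session` (or its `trials` data frame).
#' @param order_condition `"ascending"`, `"descending"` or `"random"`.
#' @param blocks optional block subset (e.g. `1` for the first ordered
#'   block; per-block denominators are 5/5/10 for asc/desc/random).
#' @return Data frame with `target_index`, `target_y`, `n`, `n_pass`,
#'   `rate`.
#' @export
pass_rate_by_target <- function(session,
                                order_condition = c("ascending", "descending",
                                                    "random"),
                                blocks = NULL) {
  order_condition <- match.arg(order_condition)
  trials <- if (inherits(session, "pp_session")) session$trials else session
  space <- if (inherits(session, "pp_session")) session$model$space else
    task_space()
  sel <- trials$order_condition == order_condition
  if (!is.null(blocks)) sel <- sel & trials$block %in% blocks
  if (!any(sel)) stop("no trials in the requested condition")
  tr <- trials[sel, ]
  n <- tabulate(tr$target_index, nbins = 20)
  np <- tabulate(tr$target_index[tr$decision == "pass"], nbins = 20)
  data.frame(target_index = 1:20, target_y = space$targets[, 2],
             n = n, n_pass = np, rate = ifelse(n > 0, np / n, NA_real_))
}

#' Interpolated pass/no-pass transition point
#'
#' Linear interpolation of the 50% crossing of the per-target pass-rate
#' curve in target-y, converted to E/A units. The crossing may fall between
#' target locations.
#'
#' @param rates numeric vector of pass rates per target.
#' @param target_y matching target y-positions (m), increasing.
#' @param reach reach used for the E/A conversion (m).
#' @return List with `transition_y` (m) and `transition_ea`; both `NA` if
#'   the rates never span 0.5.
#' @export
transition_point <- function(rates, target_y, reach) {
  stopifnot(length(rates) == length(target_y))
  ok <- !is.na(rates)
  rates <- rates[ok]; target_y <- target_y[ok]
  below <- rates < 0.5
  cross <- which(below[-length(below)] & !below[-1])
  if (length(cross) == 0) {
    # allow exact-0.5 starts or monotone-decreasing curves
    cross <- which(!below[-length(below)] & below[-1])
    if (length(cross) == 0)
      return(list(transition_y = NA_real_, transition_ea = NA_real_))
  }
  i <- cross[1]
  r0 <- rates[i]; r1 <- rates[i + 1]
  w <- (0.5 - r0) / (r1 - r0)
  y <- target_y[i] + w * (target_y[i + 1] - target_y[i])
  list(transition_y = y, transition_ea = ea_ratio(max(0, y), reach))
}

#' Transition points of a session, per order condition
#'
#' @param session a `pp_session`.
#' @param blocks optional block subset passed to [pass_rate_by_target()].
#' @return Data frame with `order_condition`, `transition_y`,
#'   `transition_ea`.
#' @export
session_transitions <- function(session, blocks = NULL) {
  reach <- session$model$space$reach
  sub <- session$trials
  if (!is.null(blocks)) sub <- sub[sub$block %in% blocks, ]
  conds <- intersect(c("ascending", "descending", "random"),
                     unique(sub$order_condition))
  out <- lapply(conds, function(cc) {
    pr <- pass_rate_by_target(session, cc, blocks = blocks)
    tp <- transition_point(pr$rate, pr$target_y, reach)
    data.frame(order_condition = cc, transition_y = tp$transition_y,
               transition_ea = tp$transition_ea)
  })
  do.call(rbind, out)
}

#' Point-biserial correlation
#'
#' Correlation between a dichotomous 0/1 series and a continuous series;
#' identical to the Pearson correlation with the 0/1 encoding.
#'
#' @param binary numeric or logical 0/1 vector (non-constant).
#' @param continuous numeric vector of the same length (non-constant).
#' @return The correlation coefficient.
#' @export
point_biserial <- function(binary, continuous) {
  binary <- as.numeric(binary)
  stopifnot(length(binary) == length(continuous))
  if (!all(binary %in% c(0, 1))) stop("binary series must be 0/1")
  if (stats::var(binary) == 0 || stats::var(continuous) == 0)
    stop("inputs must be non-constant")
  stats::cor(binary, continuous)
}

#' Tabletop occupancy heat map
#'
#' Counts trajectory samples in an `nx` by `ny` grid over rectangular
#' bounds. Out-of-bounds samples are dropped.
#'
#' @param points a 2-column matrix/data frame of sample positions, or a
#'   list of trajectory data frames (columns `x`, `y`).
#' @param nx,ny grid dimensions (>= 1). The empirical analyses used
#'   310 x 170 (pass/target) and 930 x 510 (pickup); the simulation used
#'   1240 x 680 for pickups.
#' @param bounds numeric length-4 `c(xmin, xmax, ymin, ymax)`; default the
#'   table frame `c(0, 1.5, 0, 0.89)`.
#' @return An `nx` by `ny` integer matrix of counts; attribute `n_inside`
#'   gives the number of binned samples.
#' @export
trajectory_heatmap <- function(points, nx, ny, bounds = c(0, 1.5, 0, 0.89)) {
  stopifnot(nx >= 1, ny >= 1, length(bounds) == 4,
            bounds[2] > bounds[1], bounds[4] > bounds[3])
  if (is.list(points) && !is.data.frame(points) && !is.matrix(points)) {
    points <- do.call(rbind, lapply(points, function(tr)
      cbind(tr$x, tr$y)))
  }
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  inx <- points[, 1] >= bounds[1] & points[, 1] <= bounds[2] &
    points[, 2] >= bounds[3] & points[, 2] <= bounds[4]
  pts <- points[inx, , drop = FALSE]
  ix <- pmin(nx, 1L + floor((pts[, 1] - bounds[1]) /
                              (bounds[2] - bounds[1]) * nx))
  iy <- pmin(ny, 1L + floor((pts[, 2] - bounds[3]) /
                              (bounds[4] - bounds[3]) * ny))
  grid <- matrix(0L, nx, ny)
  for (k in seq_along(ix)) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1L
  attr(grid, "n_inside") <- nrow(pts)
  grid
}

#' Optimal number of K-means clusters by Monte-Carlo reference gap
#'
#' K-means SSE for k = 1..`k_max` (multi-restart), compared with the mean
#' SSE of `n_ref` uniform reference samples drawn over the points' bounding
#' box. The optimal k maximises the reference-minus-observed SSE gap; ties
#' resolve to the smaller k.
#'
#' @param points 2-column matrix/data frame of locations.
#' @param k_max maximum k (default 3; requires at least `k_max` points).
#' @param n_ref Monte-Carlo reference replicates (default 100).
#' @param restarts K-means restarts (default 10).
#' @return List with `optimal_k`, `centers` (for the optimal k),
#'   `sse_by_k`, `reference_sse_by_k`, `gap_by_k`.
#' @export
optimal_clusters <- function(points, k_max = 3, n_ref = 100, restarts = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < k_max) stop("need at least k_max points")
  sse_k <- function(p, k) {
    if (k == 1) sum(scale(p, scale = FALSE)^2)
    else stats::kmeans(p, centers = k, nstart = restarts,
                       iter.max = 50)$tot.withinss
  }
  sse <- vapply(1:k_max, function(k) sse_k(points, k), numeric(1))
  lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  ref <- matrix(0, n_ref, k_max)
  for (r in seq_len(n_ref)) {
    q <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]))
    ref[r, ] <- vapply(1:k_max, function(k) sse_k(q, k), numeric(1))
  }
  ref_mean <- colMeans(ref)
  gap <- ref_mean - sse
  k_opt <- which.max(gap + 1e-12 * rev(seq_len(k_max)))  # ties -> smaller k
  centers <- if (k_opt == 1) matrix(colMeans(points), 1) else
    stats::kmeans(points, centers = k_opt, nstart = restarts,
                  iter.max = 50)$centers
  list(optimal_k = as.integer(k_opt), centers = centers, sse_by_k = sse,
       reference_sse_by_k = ref_mean, gap_by_k = gap)
}

#' Fit candidate distributions to radial pass-location spread
#'
#' Squared Euclidean distances of each point from the points' centroid are
#' fit by maximum likelihood to Gaussian, exponential and lognormal
#' families; a one-sample Kolmogorov-Smirnov test (asymptotic p) scores
#' each fit, and the family with the largest p wins.
#'
#' @param points 2-column matrix/data frame (>= 8 points, not all
#'   identical).
#' @param squared use squared distances (default, the empirical
#'   definition) or plain distances.
#' @return List with per-family `params`, `ks_stat`, `p_value`, and
#'   `best_family`.
#' @export
fit_radial_distribution <- function(points, squared = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < 8) stop("need at least 8 points")
  ctr <- colMeans(points)
  d2 <- (points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2
  if (all(d2 == 0)) stop("degenerate input: all points identical")
  d <- if (squared) d2 else sqrt(d2)
  d <- d[d > 0]
  mu <- mean(d); sdev <- sqrt(mean((d - mu)^2))
  lm_ <- mean(log(d)); ls <- sqrt(mean((log(d) - lm_)^2))
  fits <- list(
    gaussian = list(params = c(mean = mu, sd = sdev),
                    test = suppressWarnings(
                      stats::ks.test(d, "pnorm", mu, sdev))),
    exponential = list(params = c(rate = 1 / mu),
                       test = suppressWarnings(
                         stats::ks.test(d, "pexp", 1 / mu))),
    lognormal = list(params = c(meanlog = lm_, sdlog = ls),
                     test = suppressWarnings(
                       stats::ks.test(d, "plnorm", lm_, ls))))
  out <- lapply(fits, function(f)
    list(params = f$params, ks_stat = unname(f$test$statistic),
         p_value = f$test$p.value))
  out$best_family <- names(fits)[which.max(vapply(out, function(f)
    f$p_value, numeric(1)))]
  out
}

#' Peak speeds of every movement in a session
#'
#' Applies [velocity_profile()] to each stored trajectory.
#'
#' @param session a `pp_session` simulated with `movements = TRUE`.
#' @return Data frame with `trial_index`, `movement_class`, `peak`,
#'   `peak_fraction`.
#' @export
session_peak_speeds <- function(session) {
  if (is.null(session$trajectories))
    stop("session was simulated without movements")
  rows <- lapply(seq_along(session$trajectories), function(i) {
    trs <- session$trajectories[[i]]
    do.call(rbind, lapply(trs, function(tr) {
      vp <- velocity_profile(tr)
      data.frame(trial_index = i,
                 movement_class = attr(tr, "movement_class"),
                 peak = vp$peak, peak_fraction = vp$peak_fraction)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
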