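test_that("time normalisation yields 512 points with exact endpoints", {
  tr <- straight_traj(c(0, 0), c(1, 0.5), n = 37)
  nt <- time_normalize(tr)
  expect_equal(nrow(nt), 512)
  expect_equal(unlist(nt[1, c("x", "y")]), c(x = 0, y = 0))
  expect_equal(unlist(nt[512, c("x", "y")]), c(x = 1, y = 0.5))
  # a constant-velocity straight segment stays collinear and uniform
  expect_equal(nt$y, 0.5 * nt$x, tolerance = 1e-12)
  expect_equal(diff(nt$x), rep(diff(nt$x)[1], 511), tolerance = 1e-9)
  nt2 <- time_normalize(tr, n = 2)
  expect_equal(nt2$x, c(0, 1))
  expect_error(time_normalize(tr[1:3, ]), "4 samples")
  expect_error(time_normalize(data.frame(t = c(0, 1, 1, 2), x = 0:3,
                                         y = 0:3)), "increasing")
})

test_that("chord-deviation area: zero on the chord, signed triangle off it", {
  nt <- time_normalize(straight_traj(c(0, 0), c(1, 0), n = 20))
  expect_equal(curvature_area(nt)$area, 0, tolerance = 1e-12)
  # piecewise-linear bump (0,0) -> (0.5,0.2) -> (1,0): area = 1/2 * 1 * 0.2
  xx <- seq(0, 1, length.out = 513)  # apex is a sample point
  bump <- data.frame(t = seq_along(xx), x = xx,
                     y = stats::approx(c(0, 0.5, 1), c(0, 0.2, 0), xx)$y)
  ca <- curvature_area(bump)
  expect_equal(ca$area, 0.1, tolerance = 1e-9)
  expect_equal(ca$straight_line_angle, 0)
  # mirrored bump lies right of the chord: negative area
  bump$y <- -bump$y
  expect_equal(curvature_area(bump)$area, -0.1, tolerance = 1e-9)
  # right-to-left straight movement has initial angle 180 degrees
  nt <- time_normalize(straight_traj(c(1, 0), c(0, 0), n = 20))
  ca <- curvature_area(nt)
  expect_equal(abs(ca$initial_angle), 180)
  expect_equal(ca$deviation, ca$initial_angle - ca$straight_line_angle)
  expect_error(curvature_area(time_normalize(
    data.frame(t = 1:10, x = rep(0, 10), y = rep(0, 10)))), "chord|angle")
})

test_that("velocity profile: flat for constant speed, errors on bad time", {
  tr <- straight_traj(c(0, 0), c(2, 0), n = 41, t_end = 2)
  vp <- velocity_profile(tr)
  expect_equal(length(vp$profile), 512)
  expect_equal(vp$profile, rep(1, 512), tolerance = 1e-9)
  expect_equal(vp$peak, 1, tolerance = 1e-9)
  rev_tr <- tr[nrow(tr):1, ]
  expect_error(velocity_profile(rev_tr), "increasing")
  expect_error(velocity_profile(tr[1:3, ]), "4 samples")
})

test_that("simulated transport movements peak in the first half", {
  s <- run_session(pp_model(), seed = 21,
                   schedule = build_schedule(seed = 21)[1:40, ],
                   movements = TRUE)
  pk <- session_peak_speeds(s)
  expect_gte(mean(pk$peak_fraction < 0.5), 0.95)
})

test_that("pass rates carry the caption denominators and saturate", {
  s <- default_session_cached(seed = 1)
  pr_asc <- pass_rate_by_target(s, "ascending", blocks = 1)
  pr_desc <- pass_rate_by_target(s, "descending", blocks = 1)
  pr_rnd <- pass_rate_by_target(s, "random")
  expect_equal(pr_asc$n, rep(5, 20))
  expect_equal(pr_desc$n, rep(5, 20))
  expect_equal(pr_rnd$n, rep(10, 20))
  expect_true(all(pr_asc$rate >= 0 & pr_asc$rate <= 1))
  # saturation: no passes at the 5 nearest targets, all at the 5 farthest
  expect_equal(pr_asc$rate[1:5], rep(0, 5))
  expect_equal(pr_asc$rate[16:20], rep(1, 5))
  expect_error(pass_rate_by_target(s, "random", blocks = 1), "condition")
})

test_that("transition interpolation finds the 50% crossing", {
  ys <- task_space()$targets[, 2]
  rates <- c(rep(0, 10), rep(1, 10))
  tp <- transition_point(rates, ys, reach = 0.522)
  expect_equal(tp$transition_y, (ys[10] + ys[11]) / 2)
  expect_equal(tp$transition_ea, (ys[10] + ys[11]) / 2 / 0.522)
  expect_true(is.na(transition_point(rep(0, 20), ys, 0.522)$transition_y))
  expect_true(is.na(transition_point(rep(1, 20), ys, 0.522)$transition_y))
})

test_that("transition estimates recover the configured decision centre", {
  # sessions generated under a known sigma/delta; the estimator must land
  # within the E/A quantisation of the target grid (half-step 0.0335)
  m <- pp_model()
  st <- session_transitions(default_session_cached(seed = 13))
  asc <- st$transition_ea[st$order_condition == "ascending"]
  desc <- st$transition_ea[st$order_condition == "descending"]
  band <- critical_alpha() / m$decision$delta
  expect_lt(abs(asc - (m$decision$sigma + band)), 0.0335)
  expect_lt(abs(desc - (m$decision$sigma - band)), 0.0335)
  expect_lt(abs((asc + desc) / 2 - m$decision$sigma), 0.0335)
})

test_that("point-biserial equals Pearson and vanishes under independence", {
  set.seed(14)
  x <- stats::rnorm(200)
  b <- as.numeric(x + stats::rnorm(200) > 0)
  expect_equal(point_biserial(b, x), stats::cor(b, x))
  xi <- stats::rnorm(10000)
  bi <- stats::rbinom(10000, 1, 0.5)
  expect_lt(abs(point_biserial(bi, xi)), 0.05)
  expect_error(point_biserial(rep(1, 5), 1:5), "non-constant")
  expect_error(point_biserial(c(0, 1, 2), 1:3), "0/1")
})

test_that("decision series correlate with target, not pickup, distance", {
  s <- default_session_cached(seed = 1)
  passes <- as.numeric(s$trials$decision == "pass")
  expect_gt(point_biserial(passes, s$trials$target_index), 0.7)
  expect_lt(abs(point_biserial(passes, s$trials$pickup_index)), 0.1)
})

test_that("heat maps conserve in-bounds sample counts", {
  g <- trajectory_heatmap(matrix(c(0.2, 0.2), 1), nx = 10, ny = 5)
  expect_equal(sum(g), 1)
  expect_equal(dim(g), c(10, 5))
  set.seed(15)
  pts <- cbind(stats::runif(500, -0.2, 1.7), stats::runif(500, -0.2, 1.1))
  inside <- pts[, 1] >= 0 & pts[, 1] <= 1.5 & pts[, 2] >= 0 & pts[, 2] <= 0.89
  g <- trajectory_heatmap(pts, nx = 310, ny = 170)
  expect_equal(sum(g), sum(inside))
  g2 <- trajectory_heatmap(list(data.frame(x = c(0.1, 0.2), y = c(0.1, 0.2)),
                                data.frame(x = 0.3, y = 0.3)),
                           nx = 930, ny = 510)
  expect_equal(sum(g2), 3)
  expect_error(trajectory_heatmap(pts, nx = 10, ny = 5,
                                  bounds = c(1, 1, 0, 1)), "bounds")
})

test_that("cluster-count selection: one blob vs two separated blobs", {
  set.seed(16)
  blob <- cbind(stats::rnorm(200, 0.5, 0.01), stats::rnorm(200, 0.5, 0.01))
  oc <- optimal_clusters(blob, n_ref = 50)
  expect_equal(oc$optimal_k, 1L)
  expect_true(all(diff(oc$sse_by_k) <= 1e-9))
  two <- rbind(cbind(stats::rnorm(100, 0, 0.02), stats::rnorm(100, 0, 0.02)),
               cbind(stats::rnorm(100, 1, 0.02), stats::rnorm(100, 1, 0.02)))
  expect_equal(optimal_clusters(two, n_ref = 50)$optimal_k, 2L)
  expect_error(optimal_clusters(blob[1:2, ]), "k_max")
})

test_that("radial distribution fitting identifies a lognormal cloud", {
  hits <- 0
  for (sd in 1:10) {
    set.seed(sd)
    r <- stats::rlnorm(500, log(0.05), 0.5)
    th <- stats::runif(500, 0, 2 * pi)
    pts <- cbind(0.5 + r * cos(th), 0.5 + r * sin(th))
    fr <- fit_radial_distribution(pts)
    hits <- hits + (fr$best_family == "lognormal" &&
                      fr$lognormal$p_value > 0.1)
    expect_true(all(vapply(c("gaussian", "exponential", "lognormal"),
                           function(f) fr[[f]]$p_value, 1) >= 0))
    expect_true(all(vapply(c("gaussian", "exponential", "lognormal"),
                           function(f) fr[[f]]$p_value, 1) <= 1))
  }
  expect_gte(hits / 10, 0.9)
  expect_error(fit_radial_distribution(matrix(0.3, 10, 2)), "identical")
  expect_error(fit_radial_distribution(matrix(1:6, 3, 2)), "8 points")
})

test_that("pickup-movement curvature flips sign from nearest to farthest", {
  m <- pp_model()
  areas <- vapply(1:5, function(pk) {
    h0 <- initial_heading("pickup", pk, m$angles, noise = FALSE)
    tr <- integrate_movement(c(0, 0), h0, m$space$pickups[pk, ], m$steering,
                             m$velocity, "pickup", heading_noise = 0)
    curvature_area(time_normalize(tr))$area
  }, numeric(1))
  expect_true(sign(areas[1]) != sign(areas[5]))
  expect_true(all(diff(areas) > 0) || all(diff(areas) < 0))
})

test_that("transport initial angles are fixed by pickup, not by end point", {
  m <- pp_model()
  for (pk in c(1, 5)) {
    h1 <- initial_heading("target", pk, m$angles, noise = FALSE)
    ias <- vapply(c(1, 10, 20), function(tg) {
      tr <- integrate_movement(as.numeric(m$space$pickups[pk, ]), h1,
                               as.numeric(m$space$targets[tg, ]),
                               m$steering, m$velocity, "target",
                               heading_noise = 0)
      curvature_area(time_normalize(tr))$initial_angle
    }, numeric(1))
    expect_lt(max(ias) - min(ias), 2)
    expect_equal(mean(ias), -mean_initial_angle("target", pk, m$angles),
                 tolerance = 0.05)
  }
})
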