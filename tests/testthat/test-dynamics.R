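test_that("goal geometry returns signed angles from straight-ahead", {
  g <- goal_geometry(c(0, 0), c(0, 1))
  expect_equal(g$distance, 1)
  expect_equal(g$goal_angle, 0)
  g <- goal_geometry(c(0, 0), c(3, 4))
  expect_equal(g$distance, 5)
  expect_equal(g$goal_angle, 0.6435011, tolerance = 1e-6)
  # goals to the left carry the opposite sign
  expect_equal(goal_geometry(c(0, 0), c(-3, 4))$goal_angle, -0.6435011,
               tolerance = 1e-6)
  expect_error(goal_geometry(c(1, 2), c(1, 2)), "degenerate")
})

test_that("steering law: equilibrium, pure damping, and quantitative value", {
  p <- steering_params(b_g = 3.25, k_g = 7.5, c1 = 0.4, c2 = 0.4)
  geom <- list(distance = 1, goal_angle = 0.2)
  expect_equal(steering_accel(0.2, 0, geom, p), 0)
  expect_equal(steering_accel(0.2, 0.5, geom, p), -3.25 * 0.5)
  expect_equal(steering_accel(0.3, 0, geom, p), -0.802740, tolerance = 1e-6)
  # wrapping: an error of 2*pi is no error at all
  expect_equal(steering_accel(0.2 + 2 * pi, 0, geom, p), 0, tolerance = 1e-9)
})

test_that("velocity law: equilibrium, far-distance limit, goal deceleration", {
  p <- velocity_params()
  Cv <- p$C_v[["target"]]
  veq <- Cv * (1 - exp(-0.7))
  expect_equal(velocity_accel(veq, 0, 0.7, p, Cv), 0)
  expect_equal(velocity_accel(0, 0, 1e3, p, Cv), p$k_v * Cv)
  expect_equal(velocity_accel(0.5, 0, 0, p, Cv), -p$k_v * 0.5)
  expect_error(velocity_accel(0, 0, -1, p), "non-negative")
})

test_that("a single step at full equilibrium only advances the position", {
  p <- velocity_params()
  st <- list(pos = c(0, 0), heading = 0, heading_rate = 0,
             speed = p$C_v[["target"]] * (1 - exp(-10)), speed_rate = 0)
  new <- step_state(st, goal = c(0, 10), velocity = p, dt = 0.01)
  expect_equal(new$heading, 0)
  expect_equal(new$heading_rate, 0)
  expect_equal(new$pos, c(0, st$speed * 0.01))
  # speed equilibrium shifts only because the distance shrank
  expect_equal(new$speed, st$speed)
})

test_that("stepping is deterministic under a fixed seed", {
  st <- list(pos = c(0, 0), heading = 0.3, heading_rate = 0, speed = 0.5,
             speed_rate = 0)
  set.seed(9)
  a <- step_state(st, c(0.5, 0.5), heading_noise = 0.02)
  set.seed(9)
  b <- step_state(st, c(0.5, 0.5), heading_noise = 0.02)
  expect_identical(a, b)
})

test_that("Euler at dt = 0.01 agrees with an RK4 reference within 1 cm", {
  ts <- task_space()
  sp <- steering_params(); vp <- velocity_params()
  for (case in list(list(start = c(0, 0), goal = ts$pickups[3, ],
                         cls = "pickup", a0 = 166),
                    list(start = ts$pickups[2, ], goal = ts$targets[10, ],
                         cls = "target", a0 = -5))) {
    h0 <- printed_angle_to_heading(-case$a0)  # measured-convention angle
    tr <- integrate_movement(as.numeric(case$start), h0,
                             as.numeric(case$goal), sp, vp, case$cls,
                             heading_noise = 0)
    ref <- rk4_movement(as.numeric(case$start), h0, as.numeric(case$goal),
                        sp, vp, vp$C_v[[case$cls]])
    gap <- sqrt(sum((unlist(tr[nrow(tr), c("x", "y")]) - ref$pos)^2))
    expect_lt(gap, 0.01)
  }
})

test_that("noise-free movements arrive for every pickup-target pair", {
  ts <- task_space()
  m <- pp_model()
  for (pk in 1:5) {
    h0 <- initial_heading("pickup", pk, m$angles, noise = FALSE)
    tr <- integrate_movement(c(0, 0), h0, ts$pickups[pk, ], m$steering,
                             m$velocity, "pickup", heading_noise = 0)
    expect_true(attr(tr, "arrived"))
    h1 <- initial_heading("target", pk, m$angles, noise = FALSE)
    for (tg in 1:20) {
      tr2 <- integrate_movement(as.numeric(ts$pickups[pk, ]), h1,
                                as.numeric(ts$targets[tg, ]), m$steering,
                                m$velocity, "target", heading_noise = 0)
      expect_true(attr(tr2, "arrived"))
    }
  }
})

test_that("curved start: chord-area sign follows the initial deviation sign", {
  ts <- task_space()
  goal <- as.numeric(ts$targets[10, ])
  start <- as.numeric(ts$pickups[3, ])
  straight <- goal_geometry(start, goal)$goal_angle
  for (off in c(20, -20) * pi / 180) {
    tr <- integrate_movement(start, straight + off, goal, heading_noise = 0)
    ca <- curvature_area(time_normalize(tr))
    # positive heading offset (toward +x from +y) veers right of the chord
    expect_equal(sign(ca$area), -sign(off))
  }
})

test_that("max_steps exhaustion flags non-arrival without error", {
  tr <- integrate_movement(c(0, 0), 0, c(0, 1), max_steps = 1,
                           heading_noise = 0)
  expect_false(attr(tr, "arrived"))
  expect_equal(nrow(tr), 2)
})

test_that("the heading error decays monotonically below 1 degree (far goal)", {
  # an effectively fixed goal direction isolates the steering loop itself
  tr <- integrate_movement(c(0, 0), 40 * pi / 180, c(0, 10),
                           heading_noise = 0, max_steps = 500)
  err <- abs((tr$heading - atan2(0 - tr$x, 10 - tr$y) + pi) %% (2 * pi) - pi)
  expect_true(all(diff(err) <= 1e-9))
  expect_lt(err[length(err)] * 180 / pi, 1)
})

test_that("transport heading error is non-increasing away from the goal", {
  ts <- task_space(); m <- pp_model()
  for (pk in c(1, 5)) {
    h1 <- initial_heading("target", pk, m$angles, noise = FALSE)
    tr <- integrate_movement(as.numeric(ts$pickups[pk, ]), h1,
                             as.numeric(ts$targets[15, ]), m$steering,
                             m$velocity, "target", heading_noise = 0)
    g <- attr(tr, "goal")
    d <- sqrt((g[1] - tr$x)^2 + (g[2] - tr$y)^2)
    err <- abs((tr$heading - atan2(g[1] - tr$x, g[2] - tr$y) + pi) %%
                 (2 * pi) - pi)
    far <- d > 0.1
    expect_true(all(diff(err[far]) <= 1e-6))
  }
})

test_that("speed profiles are single-peaked with the peak in the first half", {
  ts <- task_space(); m <- pp_model()
  n_ok_shape <- 0; n_ok_peak <- 0; n <- 0
  for (pk in 1:5) for (cls in c("pickup", "target")) {
    h <- initial_heading(cls, pk, m$angles, noise = FALSE)
    start <- if (cls == "pickup") c(0, 0) else as.numeric(ts$pickups[pk, ])
    goal <- if (cls == "pickup") as.numeric(ts$pickups[pk, ]) else
      as.numeric(ts$targets[12, ])
    tr <- integrate_movement(start, h, goal, m$steering, m$velocity, cls,
                             heading_noise = 0)
    dv <- diff(tr$speed)
    dv <- dv[dv != 0]
    n_ok_shape <- n_ok_shape + (sum(diff(sign(dv)) != 0) == 1)
    n_ok_peak <- n_ok_peak +
      (velocity_profile(tr)$peak_fraction < 0.5)
    n <- n + 1
  }
  expect_gte(n_ok_shape / n, 0.95)
  expect_gte(n_ok_peak / n, 0.95)
})
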