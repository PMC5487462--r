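# Independent reference implementations used as oracles in the tests.

# Fixed-step RK4 integration of the six-dimensional movement system
# (position, heading, heading rate, speed, speed rate), independent of the
# package's Euler path. No noise, no speed clamp (reference dynamics).
rk4_movement <- function(start, heading0, goal, steering, velocity, C_v,
                         dt = 1e-4, stop_radius = 0.04, t_max = 20) {
  deriv <- function(s) {
    dx <- goal[1] - s[1]; dy <- goal[2] - s[2]
    d <- sqrt(dx^2 + dy^2)
    theta <- atan2(dx, dy)
    err <- (s[3] - theta + pi) %% (2 * pi) - pi
    c(s[5] * sin(s[3]),
      s[5] * cos(s[3]),
      s[4],
      -steering$b_g * s[4] - steering$k_g * err *
        (exp(-steering$c1 * d) + steering$c2),
      s[6],
      -velocity$b_v * s[6] - velocity$k_v *
        (s[5] - C_v * (1 - exp(-d))))
  }
  s <- c(start[1], start[2], heading0, 0, 0, 0)
  t <- 0
  while (t < t_max) {
    if (sqrt((goal[1] - s[1])^2 + (goal[2] - s[2])^2) <= stop_radius) break
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  list(pos = s[1:2], t = t)
}

# Dense sign-change scan for the real roots of x - x^3 = alpha.
scan_fixed_points <- function(alpha, lo = -3, hi = 3, n = 60001) {
  xs <- seq(lo, hi, length.out = n)
  f <- xs - xs^3 - alpha
  idx <- which(f[-n] * f[-1] <= 0 & f[-n] != 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(function(x) x - x^3 - alpha, c(xs[i], xs[i + 1]),
                   tol = 1e-12)$root, numeric(1))
  unique(round(roots, 10))
}

# Straight constant-sampling trajectory helper for analysis tests.
straight_traj <- function(from, to, n = 50, t_end = 1) {
  tt <- seq(0, t_end, length.out = n)
  data.frame(t = tt,
             x = seq(from[1], to[1], length.out = n),
             y = seq(from[2], to[2], length.out = n))
}

default_session_cached <- local({
  cache <- new.env()
  function(seed = 1, movements = FALSE) {
    key <- paste0("s", seed, "_", movements)
    if (is.null(cache[[key]]))
      cache[[key]] <- run_session(pp_model(), seed = seed,
                                  movements = movements)
    cache[[key]]
  }
})
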