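# a synthetic trajectory with a prescribed tumour path, for clock tests
synthetic_traj <- function(params, Nfun, t_end = 5, n_out = 5001) {
  tt <- seq(0, t_end, length.out = n_out)
  exhaustim:::new_trajectory(
    data.frame(time = tt, Theta = 1 / params$gamma_t,
               mu = params$kappa0 / (params$kappa0 + params$gamma_t),
               N = Nfun(tt)),
    params, "reduced")
}

test_that("the exhaustion clock integrates prescribed tumour paths exactly", {
  p <- default_params()
  cl0 <- build_clock(synthetic_traj(p, function(t) 0 * t))
  expect_equal(cl0$K, p$kappa0 * cl0$time)
  expect_equal(cl0$intN, 0 * cl0$time)
  clc <- build_clock(synthetic_traj(p, function(t) rep(0.3, length(t))))
  expect_equal(clc$K, (p$kappa0 + p$kappa1 * 0.3) * clc$time)
  # a genuine trajectory: coarse-grid trapezoid vs a 40x finer independent
  # recomputation of the same integral
  traj <- simulate_reduced(p, 5, n_out = 10001)
  cl <- build_clock(traj)
  fine <- simulate_reduced(p, 5, n_out = 400001)
  Nf <- stats::approxfun(fine$time, fine$N)
  for (t in c(1.7, 3.2, 5)) {
    u <- seq(0, t, length.out = 200001)
    y <- p$kappa0 + p$kappa1 * Nf(u)
    ref <- sum(diff(u) * (y[-1] + y[-length(y)]) / 2)
    expect_equal(exhaustim:::clock_interp(cl, "K", t), ref, tolerance = 1e-8)
  }
  bad <- synthetic_traj(p, function(t) 0 * t)
  bad$time <- rev(bad$time)
  expect_error(build_clock(bad), "increasing")
})

test_that("the wavefront grows monotonically from zero towards one", {
  p <- default_params()
  cl <- build_clock(simulate_reduced(p, 100, n_out = 10001))
  S <- wavefront(cl)
  expect_equal(S[1], 0)
  expect_true(all(diff(S) > 0))
  expect_lt(max(S), 1)
  expect_gt(max(S), 0.99)
  # constant-rate closed form
  cl0 <- build_clock(synthetic_traj(default_params(kappa1 = 0),
                                    function(t) rep(0.5, length(t))))
  expect_equal(wavefront(cl0, 2), 1 - exp(-default_params()$kappa0 * 2))
})

test_that("region A reduces to the initial profile and stays stationary without tumour", {
  p <- default_params()
  cl0 <- build_clock(synthetic_traj(p, function(t) 0 * t))
  s <- seq(0.01, 0.99, length.out = 50)
  init_profile <- (1 / p$kappa0) * (1 - s)^(-(1 - p$gamma_t / p$kappa0))
  expect_equal(region_A_density(s, 0, cl0), init_profile)
  # without tumour the resident profile is stationary ahead of the front
  s_ahead <- s[s > wavefront(cl0, 4.9)]
  expect_equal(region_A_density(s_ahead, 4.9, cl0),
               (1 / p$kappa0) * (1 - s_ahead)^(-(1 - p$gamma_t / p$kappa0)))
  # wrong-region dispatch is rejected
  cl <- build_clock(simulate_reduced(p, 10, n_out = 5001))
  S <- wavefront(cl, 8)
  expect_error(region_A_density(S / 2, 8, cl), "region A")
  expect_error(infiltration_time(S + 0.01, 8, cl), "region B")
})

test_that("infiltration times invert the exhaustion clock", {
  p <- default_params()
  traj <- simulate_reduced(p, 10, n_out = 10001)
  cl <- build_clock(traj)
  expect_equal(infiltration_time(0, 7, cl), 7)
  # plugging t0 back into the clock recovers s
  set.seed(3)
  for (i in 1:20) {
    t <- stats::runif(1, 2, 10)
    S <- wavefront(cl, t)
    s <- stats::runif(1, 0, S * 0.999)
    t0 <- infiltration_time(s, t, cl)
    expect_true(t0 >= 0 && t0 <= t)
    s_rec <- 1 - exp(-(exhaustim:::clock_interp(cl, "K", t) -
                         exhaustim:::clock_interp(cl, "K", t0)))
    expect_lt(abs(s_rec - s), 1e-8)
  }
  # constant-rate closed form for the infiltration delay
  p0 <- default_params(kappa1 = 0)
  cl0 <- build_clock(synthetic_traj(p0, function(t) rep(0.2, length(t))))
  expect_equal(infiltration_time(0.15, 4, cl0), 4 + log(0.85) / p0$kappa0,
               tolerance = 1e-12)
})

test_that("region B reduces to the boundary condition at s = 0", {
  p <- default_params()
  traj <- simulate_reduced(p, 10, n_out = 10001)
  cl <- build_clock(traj)
  for (t in c(3, 6, 9)) {
    Nt <- stats::approx(traj$time, traj$N, xout = t)$y
    bc <- influx_rate(Nt, p) / exhaustion_rate(Nt, p)
    expect_equal(region_B_density(0, t, cl), bc, tolerance = 1e-9)
  }
  # strong-exhaustion regime: density grows like 1/(1-s) towards the
  # exhausted end, where the infiltration delay is negligible
  p_esc <- default_params(kappa1 = 80)
  cl_esc <- build_clock(simulate_reduced(p_esc, 10, n_out = 10001))
  expect_gt(wavefront(cl_esc, 9), 0.999)
  v <- region_B_density(c(0.9, 0.99), 9, cl_esc)
  expect_gt(v[2], 5 * v[1])
})

test_that("the constant-rate characteristics equal the explicit closed form", {
  p <- default_params(kappa1 = 0)
  t_eval <- 25 * 0.18
  traj <- simulate_reduced(p, t_eval * 1.01, n_out = 10001)
  s <- seq(0, 0.999, length.out = 401)
  dens <- evaluate_density(s, t_eval, p, traj)
  e38 <- explicit_constant_rate_density(s, t_eval, p, traj)
  front <- 1 - exp(-p$kappa0 * t_eval)
  off <- abs(s - front) > 1e-3
  expect_lt(max(abs(dens$values[off, 1] - e38[off]) /
                  pmax(abs(e38[off]), 1e-12)), 1e-10)
  expect_error(explicit_constant_rate_density(s, t_eval, default_params(), traj),
               "kappa1")
  # without tumour both branches collapse to the initial profile
  traj0 <- synthetic_traj(p, function(t) 0 * t)
  e0 <- explicit_constant_rate_density(s, 2, p, traj0)
  expect_equal(e0, (1 / p$kappa0) * (1 - s)^(-(1 - p$gamma_t / p$kappa0)))
})

test_that("region dispatch is consistent and the density solves the transport PDE", {
  p <- default_params()
  t_pts <- c(2, 4.5, 9)
  traj <- simulate_reduced(p, 10, n_out = 20001)
  s <- seq(0, 0.997, length.out = 800)
  dens <- evaluate_density(s, t_pts, p, traj)
  for (j in seq_along(t_pts))
    expect_identical(dens$region[, j] == "B", s < dens$wavefront[j])
  expect_true(all(dens$values >= 0))
  # finite-difference residual of dT/dt + d(vT)/ds + gamma T on smooth
  # interior points away from the front
  clock <- dens$clock
  t0 <- 4.5; dt <- 1e-4; ds <- s[2] - s[1]
  d_mid <- evaluate_density(s, c(t0 - dt, t0, t0 + dt), p, traj)
  S <- d_mid$wavefront[2]
  Nt <- stats::approx(traj$time, traj$N, xout = t0)$y
  k <- exhaustion_rate(Nt, p)
  v <- k * (1 - s)
  Tt <- (d_mid$values[, 3] - d_mid$values[, 1]) / (2 * dt)
  vT <- v * d_mid$values[, 2]
  Ts <- c(NA, (vT[-(1:2)] - vT[1:(length(s) - 2)]) / (2 * ds), NA)
  resid <- Tt + Ts + p$gamma_t * d_mid$values[, 2]
  interior <- which(!is.na(resid) & abs(s - S) > 0.05 & s < 0.9)
  scale <- pmax(abs(d_mid$values[interior, 2]), 1)
  expect_lt(max(abs(resid[interior]) / scale), 1e-3)
})

test_that("the discrete model converges to the continuum solution as n grows", {
  p <- default_params()
  res <- compare_with_discrete(p, 25 * 0.18, n_values = c(10, 100))
  expect_lt(res$l1_error[2], res$l1_error[1])
  # strong-exhaustion regime: the front has swept much further
  p_esc <- default_params(kappa1 = 80)
  cl_def <- build_clock(simulate_reduced(p, 25 * 0.18, n_out = 5001))
  cl_esc <- build_clock(simulate_reduced(p_esc, 25 * 0.18, n_out = 5001))
  expect_gt(wavefront(cl_esc, 25 * 0.18), wavefront(cl_def, 25 * 0.18))
})
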