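test_that("tumour-free eigenvalues and the transcritical threshold", {
  p <- default_params()
  ev <- trivial_eigenvalues(p)
  expect_equal(sort_complex(ev$alphas),
               sort_complex(as.complex(c(-p$gamma_t, -(p$gamma_t + p$kappa0),
                                         1 - f_of_N(0, p)))))
  expect_false(ev$stable)            # default: f(0) < 1, elimination unstable
  expect_true(trivial_eigenvalues(default_params(lam_t = 0.29))$stable)
  expect_equal(lambda_transcritical(p), p$gamma_t + p$kappa0)
  expect_equal(lambda_transcritical(default_params(kappa0 = 1e-12)),
               p$gamma_t, tolerance = 1e-10)
  # stability flips exactly at the threshold
  lam_tr <- lambda_transcritical(p)
  expect_false(trivial_eigenvalues(default_params(lam_t = lam_tr * (1 - 1e-9)))$stable)
  expect_true(trivial_eigenvalues(default_params(lam_t = lam_tr * (1 + 1e-9)))$stable)
})

test_that("g is the stability indicator and degenerates correctly", {
  # without tumour-dependent rates every nontrivial state is stable
  p0 <- default_params(kappa1 = 0, sigma_t = 0)
  expect_equal(g_of_N(0.5, p0), -p0$gamma_t - p0$kappa0)
  p <- default_params()
  st <- find_steady_states(p)
  for (i in 2:nrow(st)) {
    J <- numerical_jacobian(unlist(st[i, c("Theta_star", "mu_star", "N_star")]), p)
    ev <- eigen(J, only.values = TRUE)$values
    led <- max(Re(ev[abs(ev + p$gamma_t) > 1e-4]))
    expect_equal(sign(g_of_N(st$N_star[i], p)), sign(led))
  }
})

test_that("analytic eigenvalues match finite-difference Jacobians at random steady states", {
  found <- 0
  i <- 0
  samples <- sample_parameters(2024, count = 500)
  while (found < 100 && i < length(samples)) {
    i <- i + 1
    p <- nondimensionalise(samples[[i]])
    roots <- exhaustim:::positive_steady_roots(p)
    for (r in roots) {
      ev <- nontrivial_eigenvalues(r, p)
      expect_true(any(abs(ev$alphas + p$gamma_t) < 1e-12))
      th <- steady_theta_mu(r, p)
      J <- numerical_jacobian(c(th$Theta_star, th$mu_star, r), p)
      num <- sort_complex(eigen(J, only.values = TRUE)$values)
      expect_equal(sort_complex(ev$alphas), sort_complex(as.complex(num)),
                   tolerance = 1e-6)
      found <- found + 1
    }
    # trivial state too
    ev0 <- trivial_eigenvalues(p)
    J0 <- numerical_jacobian(c(1 / p$gamma_t,
                               p$kappa0 / (p$kappa0 + p$gamma_t), 0), p)
    expect_equal(sort_complex(ev0$alphas),
                 sort_complex(as.complex(eigen(J0, only.values = TRUE)$values)),
                 tolerance = 1e-6)
  }
  expect_gte(found, 100)
})

test_that("the default equilibrium attractor is an oscillatory focus", {
  p <- default_params()
  st <- find_steady_states(p)
  eq <- st[st$outcome == "equilibrium", ]
  ev <- nontrivial_eigenvalues(eq$N_star, p)
  quad <- ev$alphas[abs(ev$alphas + p$gamma_t) > 1e-12]
  expect_true(all(abs(Im(quad)) > 0))  # complex pair: damped oscillations
  expect_true(ev$stable)
})

test_that("kill-rate branch has two folds bracketing a bistable window", {
  p <- default_params()
  br <- branch_in_lambda(p)
  expect_equal(nrow(br$folds), 2)
  lam_f <- sort(br$folds$param)
  expect_lt(lam_f[1], lam_f[2])
  expect_equal(br$transcritical, lambda_transcritical(p))
  # the branch limits to the transcritical value as N* -> 0
  tiny <- branch_in_lambda(p, N_grid = seq(1e-9, 1e-6, length.out = 11))
  expect_equal(tiny$points$param[1], lambda_transcritical(p),
               tolerance = 1e-5)
  # every branch point satisfies the steady-state balance
  idx <- seq(1, nrow(br$points), by = 100)
  for (i in idx) {
    q <- p; q$lam_t <- br$points$param[i]
    expect_lt(abs(1 - br$points$N_star[i] - f_of_N(br$points$N_star[i], q)),
              1e-10)
  }
  # folds satisfy g = 0 under their own branch parameter
  for (i in seq_len(nrow(br$folds))) {
    q <- p; q$lam_t <- br$folds$param[i]
    expect_lt(abs(g_of_N(br$folds$N_star[i], q)), 1e-6)
  }
  # bistability between the folds, monostability outside
  count_stable <- function(lam) {
    q <- p; q$lam_t <- lam
    sum(exhaustim:::classify_parameter_point(q)$n_stable)
  }
  expect_equal(count_stable(sqrt(prod(lam_f))), 2)
  expect_equal(count_stable(lam_f[1] * 0.5), 1)
})

test_that("exhaustion-rate branch fold count depends on elimination stability", {
  # unstable elimination (default kill rate): two folds, bistable between
  bk <- branch_in_kappa1(default_params())
  expect_equal(nrow(bk$folds), 2)
  k_f <- sort(bk$folds$param)
  expect_true(1.39 > k_f[1] && 1.39 < k_f[2])
  # stable elimination (lam_t = 0.29): a single fold, bistable above it
  bk2 <- branch_in_kappa1(default_params(lam_t = 0.29))
  expect_equal(nrow(bk2$folds), 1)
  q <- default_params(lam_t = 0.29, kappa1 = bk2$folds$param * 2)
  cl <- exhaustim:::classify_parameter_point(q)
  expect_equal(cl$n_stable, 2)
  expect_setequal(cl$stable_outcomes, c("elimination", "escape"))
  # each fold satisfies the balance and g = 0 simultaneously
  for (i in seq_len(nrow(bk$folds))) {
    q <- default_params(kappa1 = bk$folds$param[i])
    expect_lt(abs(1 - bk$folds$N_star[i] - f_of_N(bk$folds$N_star[i], q)), 1e-8)
    expect_lt(abs(g_of_N(bk$folds$N_star[i], q)), 1e-6)
  }
})

test_that("three folds appear above the transcritical point in the tristable regime", {
  p <- default_params(sigma_t = 3.3, N_t = 0.45)
  br <- branch_in_lambda(p)
  expect_equal(nrow(br$folds), 3)
  lam_f <- sort(br$folds$param)
  expect_true(lambda_transcritical(p) < lam_f[1])
  expect_true(lam_f[1] < lam_f[2] && lam_f[2] < lam_f[3])
})

test_that("a coarse region map recovers the five qualitative regions", {
  p <- default_params()
  rm_ <- region_map(p, resolution = 60)
  expect_equal(length(rm_$classes), 5)
  expect_true(all(rm_$grid$total <= 5))
  cell_class <- function(lam, k1) {
    q <- p; q$lam_t <- lam; q$kappa1 <- k1
    cl <- exhaustim:::classify_parameter_point(q)
    cl$stable_outcomes
  }
  expect_equal(cell_class(0.29, 1.39), "elimination")
  expect_setequal(cell_class(0.0442, 1.39), c("equilibrium", "escape"))
  expect_equal(cell_class(0.0442, 80), "escape")
})

test_that("the tristable window supports three simultaneous attractors", {
  p <- default_params()
  tri <- tristability_window(
    p, rbind(c(1885, 0.04), c(3.3, 0.45)), n_sweep = 2000)
  expect_equal(tri$max_states, c(4, 5))
  expect_false(tri$tristable[1])
  expect_true(tri$tristable[2])
  # simulations started near each stable state stay with it
  q <- default_params(sigma_t = 3.3, N_t = 0.45,
                      lam_t = sqrt(tri$lam_lo[2] * tri$lam_hi[2]))
  st <- find_steady_states(q)
  stable <- st[st$stable, ]
  expect_equal(nrow(stable), 3)
  for (i in seq_len(3)) {
    s0 <- c(Theta = stable$Theta_star[i], mu = stable$mu_star[i],
            N = max(stable$N_star[i] * 1.01, 1e-4))
    traj <- simulate_reduced(q, 300, state0 = s0)
    fin <- unlist(traj[nrow(traj), c("Theta", "mu", "N")])
    d <- abs(stable$N_star - fin["N"])
    expect_equal(which.min(d), i)
  }
})
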