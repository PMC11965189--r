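# shared fixtures and oracles for the test suite

# literature defaults with selective overrides (bypasses the constructor so
# tests can probe degenerate corners deliberately)
default_params <- function(...) {
  p <- dimensionless_parameters()
  mod <- list(...)
  for (nm in names(mod)) p[[nm]] <- mod[[nm]]
  p
}

rel_err <- function(a, b, floor = 1e-8) max(abs(a - b) / pmax(abs(b), floor))

# central-difference Jacobian of the reduced right-hand side at a state
numerical_jacobian <- function(state, params, h = 1e-7) {
  f <- function(x) reduced_rhs(x, params)
  J <- matrix(0, 3, 3)
  for (i in 1:3) {
    hp <- h * max(1, abs(state[i]))
    up <- state; up[i] <- state[i] + hp
    dn <- state; dn[i] <- state[i] - hp
    J[, i] <- (f(up) - f(dn)) / (2 * hp)
  }
  J
}

sort_complex <- function(z) z[order(Re(z), Im(z))]

# independent root scan of 1 - N - f(N) by dense bracketing + uniroot
scan_steady_roots <- function(params, n_grid = 1e5) {
  h <- function(N) 1 - N - f_of_N(N, params)
  N <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  y <- h(N)
  idx <- which(y[-1] * y[-length(y)] < 0)
  vapply(idx, function(i)
    stats::uniroot(h, c(N[i], N[i + 1]), tol = 1e-13)$root, numeric(1))
}
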