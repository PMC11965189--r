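#' Dimensional parameter set for the tumour-immune exhaustion model
#'
#' Bundles the ten dimensional quantities that define the model: tumour growth
#' and carrying capacity, per-T-cell kill rate, basal and tumour-stimulated
#' T-cell influx, the tumour size at which influx peaks, basal and
#' tumour-enhanced exhaustion rates, T-cell death rate, and the initial tumour
#' size. All rates are per day, all cell quantities are absolute counts.
#'
#' @param r tumour growth rate (day^-1).
#' @param K tumour carrying capacity (cells).
#' @param lam per-T-cell tumour kill rate (day^-1 cells^-1).
#' @param sigma0 basal T-cell influx (cells day^-1).
#' @param sigma1 tumour-stimulated influx coefficient (day^-1).
#' @param Nbar tumour size at which T-cell influx is maximal (cells).
#' @param k0 basal T-cell exhaustion rate (day^-1).
#' @param k1 tumour-enhanced exhaustion rate (cells^-1 day^-1).
#' @param gamma natural T-cell death rate (day^-1).
#' @param N0hat initial number of tumour cells (cells); must not exceed `K`.
#'
#' @return An object of class `"dimensional_parameters"`.
#' @examples
#' p <- dimensional_parameters()
#' nondimensionalise(p)
#' @seealso [dimensionless_parameters()], [nondimensionalise()]
#' @export
dimensional_parameters <- function(r = 0.18, K = 5e8, lam = 1.101e-7,
                                   sigma0 = 1.3e4, sigma1 = 0.049,
                                   Nbar = 2e7, k0 = 0.01, k1 = 5e-10,
                                   gamma = 0.0412, N0hat = 1e7) {
  p <- list(r = r, K = K, lam = lam, sigma0 = sigma0, sigma1 = sigma1,
            Nbar = Nbar, k0 = k0, k1 = k1, gamma = gamma, N0hat = N0hat)
  validate_dimensional(p)
  structure(p, class = "dimensional_parameters")
}

validate_dimensional <- function(p) {
  for (nm in c("r", "K", "lam", "sigma0", "sigma1", "Nbar", "k0", "k1",
               "gamma", "N0hat")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dimensional parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (p$N0hat > p$K)
    stop("initial tumour size 'N0hat' exceeds carrying capacity 'K'",
         call. = FALSE)
  invisible(p)
}

#' Dimensionless parameter set
#'
#' The six dimensionless groupings that govern the scaled model, together with
#' the initial dimensionless tumour burden `N0` and the number of exhaustion
#' compartments `n`. These can be supplied directly, or derived from a
#' dimensional set with [nondimensionalise()].
#'
#' @param lam_t dimensionless T-cell kill rate.
#' @param sigma_t dimensionless tumour-stimulated influx rate.
#' @param N_t tumour burden (fraction of carrying capacity) at which T-cell
#'   influx is maximal.
#' @param kappa0 dimensionless basal exhaustion rate.
#' @param kappa1 dimensionless tumour-enhanced exhaustion rate.
#' @param gamma_t dimensionless T-cell death rate.
#' @param N0 initial tumour burden as a fraction of carrying capacity, in
#'   (0, 1].
#' @param n number of exhaustion compartments beyond the fully active class
#'   (the structured model tracks `n + 1` subpopulations). Default 10.
#' @param r optional tumour growth rate (day^-1) used to convert between
#'   dimensionless time and days (e.g. for treatment schedules); defaults to
#'   0.18 when not supplied.
#'
#' @return An object of class `"dimensionless_parameters"`.
#' @export
dimensionless_parameters <- function(lam_t = 0.0442, sigma_t = 1885,
                                     N_t = 0.04, kappa0 = 0.0556,
                                     kappa1 = 1.39, gamma_t = 0.229,
                                     N0 = 0.02, n = 10L, r = NULL) {
  p <- list(lam_t = lam_t, sigma_t = sigma_t, N_t = N_t, kappa0 = kappa0,
            kappa1 = kappa1, gamma_t = gamma_t, N0 = N0, n = as.integer(n),
            r = if (is.null(r)) NA_real_ else r)
  validate_dimensionless(p)
  structure(p, class = "dimensionless_parameters")
}

validate_dimensionless <- function(p) {
  for (nm in c("lam_t", "N_t", "kappa0", "gamma_t")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dimensionless parameter '", nm,
           "' must be a single positive number", call. = FALSE)
  }
  # kappa1 and sigma_t may be exactly zero (constant exhaustion rate / no
  # tumour-stimulated influx), which several analytic limits rely on
  for (nm in c("sigma_t", "kappa1")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("dimensionless parameter '", nm,
           "' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(p$N0) || length(p$N0) != 1L || p$N0 <= 0 || p$N0 > 1)
    stop("initial tumour burden 'N0' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(p$n) || length(p$n) != 1L || p$n < 1 || p$n != round(p$n))
    stop("compartment count 'n' must be a positive integer", call. = FALSE)
  if (!is.na(p$r) && p$r <= 0)
    stop("growth rate 'r' must be positive when supplied", call. = FALSE)
  invisible(p)
}

#' Convert a dimensional parameter set to dimensionless form
#'
#' Applies the scalings t -> r*t_hat, N -> N_hat/K, Theta -> (r/sigma0) *
#' Theta_hat, which produce the groupings lam_t = lam*sigma0/r^2, sigma_t =
#' sigma1*K/sigma0, N_t = Nbar/K, kappa0 = k0/r, kappa1 = k1*K/r, gamma_t =
#' gamma/r, and N0 = N0hat/K. The dimensional growth rate `r` is carried along
#' so trajectories can later be re-dimensionalised.
#'
#' @param p a [dimensional_parameters()] object.
#' @param n number of exhaustion compartments (default 10).
#' @return A [dimensionless_parameters()] object.
#' @export
nondimensionalise <- function(p, n = 10L) {
  stopifnot(inherits(p, "dimensional_parameters"))
  validate_dimensional(p)
  dimensionless_parameters(
    lam_t   = p$lam * p$sigma0 / p$r^2,
    sigma_t = p$sigma1 * p$K / p$sigma0,
    N_t     = p$Nbar / p$K,
    kappa0  = p$k0 / p$r,
    kappa1  = p$k1 * p$K / p$r,
    gamma_t = p$gamma / p$r,
    N0      = p$N0hat / p$K,
    n       = n,
    r       = p$r)
}

#' Re-dimensionalise a simulated trajectory
#'
#' Converts a dimensionless trajectory back to days and absolute cell counts:
#' time is divided by the growth rate `r`, tumour burden is multiplied by the
#' carrying capacity `K`, and the T-cell total by `sigma0 / r`. The mean
#' exhaustion level is already dimensionless and is left untouched.
#'
#' @param traj a trajectory from [simulate_reduced()] or [simulate_discrete()].
#' @param p the [dimensional_parameters()] object the trajectory's parameters
#'   were derived from. An error is raised if the trajectory's dimensionless
#'   parameters do not match `nondimensionalise(p)`.
#' @return A data frame with columns `t_days`, `N_cells`, and (for reduced
#'   trajectories) `T_cells` and `mu`; for compartment trajectories the
#'   `T<j>` columns are scaled to absolute counts.
#' @export
redimensionalise_trajectory <- function(traj, p) {
  stopifnot(inherits(traj, "exhaustion_trajectory"),
            inherits(p, "dimensional_parameters"))
  q <- attr(traj, "params")
  q2 <- nondimensionalise(p, n = q$n)
  for (nm in c("lam_t", "sigma_t", "N_t", "kappa0", "kappa1", "gamma_t", "N0")) {
    if (abs(q[[nm]] - q2[[nm]]) > 1e-12 * abs(q2[[nm]]))
      stop("trajectory was not produced from this dimensional parameter set ",
           "(grouping '", nm, "' differs)", call. = FALSE)
  }
  out <- data.frame(t_days = traj$time / p$r)
  if (attr(traj, "kind") == "reduced") {
    out$T_cells <- traj$Theta * p$sigma0 / p$r
    out$mu <- traj$mu
    out$N_cells <- traj$N * p$K
  } else {
    tc <- grep("^T[0-9]+$", names(traj), value = TRUE)
    for (nm in tc) out[[nm]] <- traj[[nm]] * p$sigma0 / p$r
    out$N_cells <- traj$N * p$K
  }
  out
}

#' Sample random dimensional parameter sets
#'
#' Draws parameter sets from the literature ranges used to parameterise the
#' model. Quantities whose range spans at least two orders of magnitude
#' (`K`, `lam`, `k1`) are drawn log-uniformly; the rest uniformly. `sigma0`
#' and `Nbar`, for which single literature values are used, are held fixed.
#' Draws violating `N0hat <= K` cannot occur (the ranges do not overlap that
#' way), and every sample passes [dimensional_parameters()] validation.
#'
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param count number of parameter sets to draw.
#' @return A list of [dimensional_parameters()] objects.
#' @export
sample_parameters <- function(seed, count = 1L) {
  stopifnot(length(count) == 1L, count >= 1)
  rng <- local({
    set.seed(as.integer(seed))
    function(k) stats::runif(k)
  })
  runifl <- function(k, lo, hi) exp(log(lo) + (log(hi) - log(lo)) * rng(k))
  runifu <- function(k, lo, hi) lo + (hi - lo) * rng(k)
  out <- vector("list", count)
  for (i in seq_len(count)) {
    out[[i]] <- dimensional_parameters(
      r      = runifu(1, 0.1, 0.5),
      K      = runifl(1, 1e8, 1e10),
      lam    = runifl(1, 1e-8, 1e-4),
      sigma0 = 1.3e4,
      sigma1 = runifu(1, 0.001, 0.05),
      Nbar   = 2e7,
      k0     = runifu(1, 0.001, 0.01),
      k1     = runifl(1, 1e-11, 1e-8),
      gamma  = runifu(1, 0.02, 0.05),
      N0hat  = runifu(1, 1e7, 1e8))
  }
  out
}

#' Read a parameter file
#'
#' Accepts a flat YAML or JSON key-value file holding either a dimensional set
#' (keys `r, K, lam, sigma0, sigma1, Nbar, k0, k1, gamma, N0hat`) or a
#' dimensionless set (keys `lam_t, sigma_t, N_t, kappa0, kappa1, gamma_t, N0`
#' and optionally `n`, `r`). The two forms are distinguished by their keys.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [dimensional_parameters()] or [dimensionless_parameters()] object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  dim_keys <- c("r", "K", "lam", "sigma0", "sigma1", "Nbar", "k0", "k1",
                "gamma", "N0hat")
  ndim_keys <- c("lam_t", "sigma_t", "N_t", "kappa0", "kappa1", "gamma_t", "N0")
  if (all(dim_keys %in% names(vals))) {
    do.call(dimensional_parameters, lapply(vals[dim_keys], as.numeric))
  } else if (all(ndim_keys %in% names(vals))) {
    extra <- intersect(c("n", "r"), names(vals))
    args <- lapply(vals[c(ndim_keys, extra)], as.numeric)
    do.call(dimensionless_parameters, args)
  } else {
    missing_d <- setdiff(dim_keys, names(vals))
    missing_n <- setdiff(ndim_keys, names(vals))
    stop("parameter file is neither a complete dimensional set (missing: ",
         paste(missing_d, collapse = ", "),
         ") nor a complete dimensionless set (missing: ",
         paste(missing_n, collapse = ", "), ")", call. = FALSE)
  }
}

#' Write a parameter file
#'
#' Inverse of [read_parameters()]; floating-point values survive a write/read
#' round trip bit-exactly (JSON is written with full precision).
#'
#' @param p a parameter object from [dimensional_parameters()] or
#'   [dimensionless_parameters()].
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, c("dimensional_parameters", "dimensionless_parameters")))
  vals <- unclass(p)
  if (inherits(p, "dimensionless_parameters") && is.na(vals$r)) vals$r <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = I(17))
  } else {
    # 17 significant digits keep YAML round trips exact; %.17g avoids the
    # bare "2e+07" form that YAML would read back as a string
    txt <- vapply(names(vals), function(nm) {
      v <- vals[[nm]]
      s <- if (is.integer(v)) as.character(v) else sprintf("%.17g", v)
      # integral doubles must carry a decimal point or YAML reads them as
      # (possibly overflowing) integers
      if (!is.integer(v) && !grepl("[.e]", s)) s <- paste0(s, ".0")
      paste0(nm, ": ", s)
    }, character(1))
    writeLines(txt, path)
  }
  invisible(path)
}

#' @export
print.dimensional_parameters <- function(x, ...) {
  cat("Dimensional tumour-immune parameters\n")
  lab <- c(r = "day^-1", K = "cells", lam = "day^-1 cells^-1",
           sigma0 = "cells day^-1", sigma1 = "day^-1", Nbar = "cells",
           k0 = "day^-1", k1 = "cells^-1 day^-1", gamma = "day^-1",
           N0hat = "cells")
  for (nm in names(lab))
    cat(sprintf("  %-7s %-12.6g %s\n", nm, x[[nm]], lab[[nm]]))
  invisible(x)
}

#' @export
print.dimensionless_parameters <- function(x, ...) {
  cat("Dimensionless tumour-immune parameters (n =", x$n, "compartments)\n")
  for (nm in c("lam_t", "sigma_t", "N_t", "kappa0", "kappa1", "gamma_t", "N0"))
    cat(sprintf("  %-8s %.6g\n", nm, x[[nm]]))
  if (!is.na(x$r)) cat(sprintf("  (time scale: r = %.4g day^-1)\n", x$r))
  invisible(x)
}

# growth rate used for day<->dimensionless-time conversion; defaults to the
# literature value when the parameter set was supplied directly in
# dimensionless form
growth_rate <- function(params) if (is.na(params$r)) 0.18 else params$r
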