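#' Run a named reference scenario
#'
#' Reproduces the package's canonical simulation settings: the three
#' qualitative regimes (elimination at lam_t = 0.29, equilibrium at the
#' default lam_t = 0.0442, escape at kappa1 = 80) over 250 days, and the two
#' treatment scenarios (a responsive tumour at kappa1 = 1.39 and a refractory
#' one at kappa1 = 2.0, both treated with delta_kappa = 1.2 starting on day
#' 100 and initialised at the escape steady state).
#'
#' @param name one of `"elimination"`, `"equilibrium"`, `"escape"`,
#'   `"treatment_responsive"`, `"treatment_refractory"`.
#' @param out_dir optional directory; when given, the reduced and compartment
#'   trajectories and (for treatment scenarios) the kappa1(t) trace are
#'   written as CSV files there.
#' @return A list with `reduced` and `discrete` trajectories, the `outcome`
#'   label, and (for treatment runs) the schedule.
#' @export
run_scenario <- function(name, out_dir = NULL) {
  known <- c("elimination", "equilibrium", "escape",
             "treatment_responsive", "treatment_refractory")
  if (!name %in% known)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(known, collapse = ", "), call. = FALSE)
  params <- dimensionless_parameters()
  sched <- NULL
  state0 <- NULL
  dstate0 <- NULL
  t_days <- 250
  if (name == "elimination") params$lam_t <- 0.29
  if (name == "escape") params$kappa1 <- 80
  if (startsWith(name, "treatment")) {
    if (name == "treatment_refractory") params$kappa1 <- 2.0
    sched <- treatment_schedule(delta_kappa = 1.2)
    t_days <- 300
    st <- find_steady_states(params)
    esc <- st[st$outcome == "escape" & st$stable, , drop = FALSE]
    if (nrow(esc) == 0) stop("no stable escape state to initialise from",
                             call. = FALSE)
    state0 <- c(Theta = esc$Theta_star[1], mu = esc$mu_star[1],
                N = esc$N_star[1])
    sd <- steady_distribution(esc$N_star[1], params)
    dstate0 <- stats::setNames(c(sd$masses, esc$N_star[1]),
                               c(paste0("T", 0:params$n), "N"))
  }
  t_end <- t_days * growth_rate(params)
  red <- simulate_reduced(params, t_end, sched = sched, state0 = state0)
  dis <- simulate_discrete(params, t_end, sched = sched, state0 = dstate0)
  outcome <- classify_outcome(red)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(red, file.path(out_dir, paste0(name, "_reduced.csv")))
    write_trajectory_csv(dis, file.path(out_dir, paste0(name, "_discrete.csv")))
    if (!is.null(sched)) {
      td <- red$time / growth_rate(params)
      utils::write.csv(
        data.frame(t_days = td,
                   kappa1 = kappa1_at_time(td, params$kappa1, sched)),
        file.path(out_dir, paste0(name, "_kappa1.csv")), row.names = FALSE)
    }
  }
  list(reduced = red, discrete = dis, outcome = outcome, schedule = sched)
}

#' Write a trajectory as CSV
#'
#' Reduced trajectories are written with columns `t_days, Theta, mu, N` plus
#' `N_cells, T_cells` (absolute counts using the model's growth rate and, when
#' known, dimensional provenance); compartment trajectories in long format
#' `t_days, j, level, T_j` followed by a wide block of moments. Numbers carry
#' full double precision, and column order is fixed.
#'
#' @param traj an `exhaustion_trajectory`.
#' @param path output path.
#' @param p optional [dimensional_parameters()] for absolute cell counts;
#'   defaults to the literature values.
#' @export
write_trajectory_csv <- function(traj, path, p = dimensional_parameters()) {
  params <- attr(traj, "params")
  r <- growth_rate(params)
  if (attr(traj, "kind") == "reduced") {
    df <- data.frame(t_days = traj$time / r, Theta = traj$Theta, mu = traj$mu,
                     N = traj$N, N_cells = traj$N * p$K,
                     T_cells = traj$Theta * p$sigma0 / r)
    utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    tc <- grep("^T[0-9]+$", names(traj), value = TRUE)
    n <- length(tc) - 1L
    long <- do.call(rbind, lapply(0:n, function(j)
      data.frame(t_days = traj$time / r, j = j, level = j / n,
                 T_j = traj[[paste0("T", j)]])))
    long <- long[order(long$t_days, long$j), ]
    utils::write.csv(format(long, digits = 17, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write steady states as JSON
#'
#' @param steadies a data frame from [find_steady_states()].
#' @param path output path.
#' @export
write_steady_states_json <- function(steadies, path) {
  df <- as.data.frame(steadies)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    list(N_star = df$N_star[i], Theta_star = df$Theta_star[i],
         mu_star = df$mu_star[i], p_star = df$p_star[i],
         eigenvalues = lapply(c(df$eig1[i], df$eig2[i], df$eig3[i]),
                              function(z) list(re = Re(z), im = Im(z))),
         stable = df$stable[i], outcome = df$outcome[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
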