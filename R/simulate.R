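#' Sample per-cell activation times
#'
#' The linear increase in the number of IL-2 producing cells is modeled by a
#' uniformly distributed random delay in each simulated cell's first encounter
#' with an antigen-presenting cell.
#'
#' @param n_sim_cells number of cells (>= 1).
#' @param window numeric length-2, lower/upper delay bound in hours
#'   (default c(10, 60)).
#' @param seed integer seed; the draw is reproducible and does not disturb the
#'   global RNG state.
#' @return numeric vector of activation times (h).
#' @export
sample_activation_times <- function(n_sim_cells, window = c(10, 60), seed = 1L) {
  if (!is.numeric(n_sim_cells) || length(n_sim_cells) != 1L || n_sim_cells < 1)
    stop("n_sim_cells must be a positive integer")
  if (length(window) != 2L || window[1] < 0 || window[1] > window[2])
    stop("window must be c(lo, hi) with 0 <= lo <= hi")
  with_local_seed(seed, stats::runif(n_sim_cells, window[1], window[2]))
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic expansion of one global seed into independent per-stage /
#' per-replicate seeds, so every pipeline stage is reproducible in isolation.
#'
#' @param seed global integer seed.
#' @param k stage or replicate index (>= 0).
#' @return integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 1000003 + 12345) %%
               2147483647)
}

scalar_block <- function(p) {
  xt <- crosstalk_on(p); bo <- boost_on(p)
  c(p$K_TCR_pMHC, p$K_IL2R_pre,
    if (xt) p$sigma_TCR_inh else 0,
    p$K_IL2_pSTAT5, p$k_ag_consume, p$tau_activation, p$n_TCR_IL2Ra_max,
    p$k_receptor_deg, p$n_pSTAT5_IL2Ra_max, p$n_IL2Rb_0, p$n_IL2Rb_max,
    p$k_bind, p$k_endo, p$k_IL2_basal, p$sigma_pSTAT5_inh, p$n_Boost_total,
    if (bo) p$k_TCR_Boost else 0,
    if (bo) p$k_Boost_Boost else 0,
    if (bo) p$k_Boost_IL2 else 0,
    p$n_TCR_0, p$V, p$N_A, as.numeric(p$jak_blocked))
}

# Integrate one or more clones sharing the extracellular IL-2 pool.
# clones: list of list(p =, N_Tcell =, N_Antigen =, t_act =)
integrate_clones <- function(clones, t_end, rtol, atol, dt_out) {
  K <- length(clones)
  n_per <- vapply(clones, function(cl) cl$p$n_sim_cells, integer(1))
  M <- sum(n_per)
  clone_id <- rep(seq_len(K) - 1L, n_per)
  t_act <- unlist(lapply(clones, `[[`, "t_act"))
  S <- vapply(clones, function(cl) cl$N_Tcell / cl$p$n_sim_cells, numeric(1))

  parms <- c(K, M,
             unlist(lapply(clones, function(cl) scalar_block(cl$p))),
             S, clone_id, t_act)
  # the compiled init routine declares a fixed-length parameter buffer
  if (length(parms) > 40000)
    stop("cohort too large: packed parameter vector exceeds buffer")
  parms <- c(parms, numeric(40000 - length(parms)))

  y0 <- c(vapply(seq_len(K),
                 function(k) clones[[k]]$N_Antigen / S[k], numeric(1)),
          0,
          as.vector(t(cbind(0, rep(vapply(clones, function(cl) cl$p$n_IL2Rb_0,
                                          numeric(1)), n_per), 0, 0))))

  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::lsoda(
    y = y0, times = times, func = "il2_derivs", parms = parms,
    dllname = "il2cohort", initfunc = "il2_initmod",
    nout = 3L * M, rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ", attr(out, "istate")[1],
         ") for condition N_Tcell=",
         paste(vapply(clones, `[[`, numeric(1), "N_Tcell"), collapse = "+"),
         ", N_Antigen=",
         paste(vapply(clones, `[[`, numeric(1), "N_Antigen"), collapse = "+"))
  bad <- !is.finite(out[, -1])
  if (any(bad)) stop("ODE integration produced non-finite state values")
  list(out = unclass(out), K = K, M = M, n_per = n_per, clone_id = clone_id,
       t_act = t_act, S = S, times = times)
}

build_trajectory <- function(sol, k, cl, seed) {
  idx <- which(sol$clone_id == k - 1L)
  n <- length(idx)
  K <- sol$K; M <- sol$M
  cols_state <- function(j) 1 + K + 1 + 4 * (idx - 1) + j  # +1 for time col
  gate <- sol$out[, 1 + K + 1 + 4 * M + M + idx, drop = FALSE]
  structure(list(
    time = sol$times,
    il2_molar = pmax(sol$out[, 1 + K + 1], 0),
    n_pMHC = pmax(sol$out[, 1 + k], 0),
    n_IL2Ra = sol$out[, cols_state(1), drop = FALSE],
    n_IL2Rb = sol$out[, cols_state(2), drop = FALSE],
    n_cplx = sol$out[, cols_state(3), drop = FALSE],
    n_boost = sol$out[, cols_state(4), drop = FALSE],
    p_stat5 = sol$out[, 1 + K + 1 + 4 * M + idx, drop = FALSE],
    producing = gate,
    n_engagedTCR = sol$out[, 1 + K + 1 + 4 * M + 2 * M + idx, drop = FALSE],
    producer_count = rowSums(gate) * sol$S[k],
    t_act = sol$t_act[idx],
    condition = list(N_Tcell = cl$N_Tcell, N_Antigen = cl$N_Antigen,
                     n_sim_cells = n, seed = seed,
                     crosstalk_enabled = crosstalk_on(cl$p),
                     boost_enabled = boost_on(cl$p),
                     jak_blocked = cl$p$jak_blocked,
                     classical_mode = cl$p$classical_mode)
  ), class = "il2_trajectory")
}

#' Simulate one T-cell cohort
#'
#' Integrates the cohort ODE system from the standard initial conditions
#' (all per-cell states zero except basal IL-2Rbeta; no extracellular IL-2;
#' the full antigen dose scaled to the simulated cohort) on a fixed output
#' grid. The stiff system is solved with LSODA at the tolerances carried in
#' \code{p}.
#'
#' @param p an \code{\link{il2_params}} object (toggles select the variant;
#'   see \code{\link{set_variant}}).
#' @param N_Tcell number of T cells represented (>= 1).
#' @param N_Antigen number of antigen molecules in the culture (>= 0).
#' @param t_end simulation horizon in hours (default 150).
#' @param seed seed for activation-time sampling (default \code{p$rng_seed}).
#' @param t_act optional explicit activation times (overrides sampling).
#' @return an \code{il2_trajectory}: time grid, extracellular IL-2 (molar),
#'   per-cell receptor / complex / Boost / pSTAT5 / producing series (time by
#'   cell matrices), and the producer count scaled to \code{N_Tcell}.
#' @export
run_cohort <- function(p, N_Tcell, N_Antigen, t_end = 150,
                       seed = p$rng_seed, t_act = NULL) {
  stopifnot(inherits(p, "il2_params"))
  if (N_Tcell < 1) stop("N_Tcell must be >= 1")
  if (N_Antigen < 0) stop("N_Antigen must be >= 0")
  if (is.null(t_act))
    t_act <- sample_activation_times(p$n_sim_cells, p$activation_window, seed)
  cl <- list(p = p, N_Tcell = N_Tcell, N_Antigen = N_Antigen, t_act = t_act)
  sol <- integrate_clones(list(cl), t_end, p$rtol, p$atol, p$dt_out)
  build_trajectory(sol, 1L, cl, seed)
}

#' Simulate two T-cell clones sharing one IL-2 pool
#'
#' Each clone engages only its own cognate antigen pool; secreted IL-2 is
#' shared by all cells of both clones. Per-clone cohorts are scaled
#' independently to their population sizes.
#'
#' @param p1,p2 \code{\link{il2_params}} for each clone.
#' @param N1,N2 population sizes. \code{N2 = 0} degenerates to a single-clone
#'   culture.
#' @param Ag1,Ag2 cognate antigen molecule numbers.
#' @param t_end horizon (h).
#' @param seed seed for activation-time sampling (clone 2 uses a derived
#'   sub-seed).
#' @param t_act1,t_act2 optional explicit activation times per clone,
#'   overriding sampling (e.g. to impose exact clone symmetry).
#' @return an \code{il2_trajectory2}: shared \code{time} and \code{il2_molar},
#'   plus per-clone sub-trajectories in \code{$clone1}, \code{$clone2}.
#' @export
run_two_clone <- function(p1, p2, N1, N2, Ag1, Ag2, t_end = 150,
                          seed = p1$rng_seed, t_act1 = NULL, t_act2 = NULL) {
  stopifnot(inherits(p1, "il2_params"), inherits(p2, "il2_params"))
  t1 <- if (is.null(t_act1))
    sample_activation_times(p1$n_sim_cells, p1$activation_window, seed)
  else t_act1
  if (N2 <= 0) {
    solo <- run_cohort(p1, N1, Ag1, t_end, t_act = t1, seed = seed)
    return(structure(list(time = solo$time, il2_molar = solo$il2_molar,
                          clone1 = solo, clone2 = NULL),
                     class = "il2_trajectory2"))
  }
  t2 <- if (is.null(t_act2))
    sample_activation_times(p2$n_sim_cells, p2$activation_window,
                            derive_seed(seed, 2L))
  else t_act2
  cl1 <- list(p = p1, N_Tcell = N1, N_Antigen = Ag1, t_act = t1)
  cl2 <- list(p = p2, N_Tcell = N2, N_Antigen = Ag2, t_act = t2)
  sol <- integrate_clones(list(cl1, cl2), t_end, p1$rtol, p1$atol, p1$dt_out)
  structure(list(time = sol$times, il2_molar = pmax(sol$out[, sol$K + 2], 0),
                 clone1 = build_trajectory(sol, 1L, cl1, seed),
                 clone2 = build_trajectory(sol, 2L, cl2, seed)),
            class = "il2_trajectory2")
}

#' Summarize a trajectory
#'
#' Extracts the peak extracellular IL-2 concentration and companion summary
#' statistics from a simulated (or noisy, resampled) IL-2 time course.
#'
#' @param traj an \code{il2_trajectory}, or any list with \code{time} and
#'   \code{il2_molar} (and optionally \code{producer_count}).
#' @return list with \code{il2_max} (M), \code{tau_max} (h, grid time of the
#'   maximum), \code{total_il2_time_avg} (M; trapezoidal time integral of
#'   [IL-2] divided by the duration) and \code{cumulative_producer_time}
#'   (cell hours, left-sum of the scaled producer count; \code{NA} when the
#'   trajectory carries no producer counts).
#' @export
summarize_trajectory <- function(traj) {
  tt <- traj$time; il2 <- traj$il2_molar
  if (length(tt) < 2) stop("trajectory must have at least two time points")
  i_max <- which.max(il2)
  dt <- diff(tt)
  trap <- sum(dt * (utils::head(il2, -1) + utils::tail(il2, -1)) / 2)
  cpt <- if (!is.null(traj$producer_count))
    sum(utils::head(traj$producer_count, -1) * dt) else NA_real_
  list(il2_max = il2[i_max], tau_max = tt[i_max],
       total_il2_time_avg = trap / (tt[length(tt)] - tt[1]),
       cumulative_producer_time = cpt)
}

#' @export
print.il2_trajectory <- function(x, ...) {
  s <- summarize_trajectory(x)
  cat(sprintf(
    "IL-2 cohort trajectory: N_Tcell=%g, N_Antigen=%g, %d cells, %d points\n",
    x$condition$N_Tcell, x$condition$N_Antigen, x$condition$n_sim_cells,
    length(x$time)))
  cat(sprintf("  [IL-2]_max = %.3g M at tau_max = %.1f h\n",
              s$il2_max, s$tau_max))
  invisible(x)
}

#' Tidy data frame of a trajectory
#'
#' One row per (time, variable, cell), suitable for CSV serialization.
#'
#' @param traj an \code{il2_trajectory}.
#' @return data.frame with columns time, cell (NA for global pools),
#'   variable, value.
#' @export
trajectory_to_df <- function(traj) {
  nt <- length(traj$time)
  glob <- data.frame(
    time = rep(traj$time, 2), cell = NA_integer_,
    variable = rep(c("il2_molar", "n_pMHC"), each = nt),
    value = c(traj$il2_molar, traj$n_pMHC))
  per <- c("n_IL2Ra", "n_IL2Rb", "n_cplx", "n_boost", "p_stat5", "producing")
  n <- ncol(traj$n_IL2Ra)
  cells <- do.call(rbind, lapply(per, function(v) {
    m <- traj[[v]]
    data.frame(time = rep(traj$time, n), cell = rep(seq_len(n), each = nt),
               variable = v, value = as.vector(m))
  }))
  rbind(glob, cells)
}
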