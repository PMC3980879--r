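#' Default condition grids for the scaling sweep
#'
#' The package's reconstruction of the sweep behind the peak-IL-2 scaling law:
#' T-cell numbers spanning two decades and antigen-molecule numbers spanning
#' three decades, anchored so that the middle of the antigen axis corresponds
#' to the 25 nM peptide dose that maps to 1e8 antigen molecules, and chosen to
#' keep the sweep in the model's antigen-limited regime where IL-2 production
#' terminates within the 150 h horizon (see the methods vignette).
#'
#' @name sweep_defaults
#' @export
default_N_grid <- function() c(1e3, 1e4, 1e5)

#' @rdname sweep_defaults
#' @export
default_Ag_grid <- function() c(1e6, 1e7, 1e8, 1e9)

#' Sweep a grid of (T-cell number, antigen dose) conditions
#'
#' Runs \code{\link{run_cohort}} for every combination of population size,
#' antigen dose and activation-time seed, and collects peak-IL-2 summaries.
#'
#' @param p an \code{\link{il2_params}} object.
#' @param N_list,Ag_list condition grids (positive, non-empty). Defaults are
#'   \code{default_N_grid()} and \code{default_Ag_grid()}.
#' @param variant model variant label passed to \code{\link{set_variant}}.
#' @param n_seeds number of activation-time replicates per condition.
#' @param t_end horizon (h).
#' @param base_seed global seed from which per-replicate seeds are derived.
#' @return a \code{data.frame} (class \code{il2_sweep}) with one row per
#'   (N_Tcell, N_Antigen, seed): il2_max, tau_max, cumulative_producer_time.
#' @export
sweep_conditions <- function(p, N_list = default_N_grid(),
                             Ag_list = default_Ag_grid(),
                             variant = "full", n_seeds = 5, t_end = 150,
                             base_seed = p$rng_seed) {
  if (!length(N_list) || !length(Ag_list) || any(N_list <= 0) ||
      any(Ag_list <= 0))
    stop("N_list and Ag_list must be non-empty and positive")
  p <- set_variant(p, variant)
  grid <- expand.grid(N_Tcell = N_list, N_Antigen = Ag_list,
                      seed_rep = seq_len(n_seeds))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    seed <- derive_seed(base_seed, grid$seed_rep[i])
    tr <- run_cohort(p, grid$N_Tcell[i], grid$N_Antigen[i], t_end = t_end,
                     seed = seed)
    s <- summarize_trajectory(tr)
    data.frame(N_Tcell = grid$N_Tcell[i], N_Antigen = grid$N_Antigen[i],
               variant = variant, seed = seed, il2_max = s$il2_max,
               tau_max = s$tau_max,
               cumulative_producer_time = s$cumulative_producer_time)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("il2_sweep", "data.frame")
  out
}

#' Fit the power-law scaling of peak IL-2
#'
#' Regresses log10 of the peak IL-2 concentration on log10 of the T-cell
#' number and log10 of the antigen dose, giving the two scaling exponents of
#' the empirical law [IL-2]_max ~ N_Tcell^a * N_Antigen^b.
#'
#' Two estimators are available: ordinary least squares (default) and
#' two-component partial least squares regression (requires the mixOmics
#' package). On a full-factorial grid the covariates are orthogonal and the
#' two coincide to numerical precision.
#'
#' @param sweep an \code{il2_sweep} data frame (or any data frame with
#'   columns N_Tcell, N_Antigen, il2_max).
#' @param method \code{"ols"} or \code{"pls"}.
#' @return an \code{il2_powerlaw_fit}: exponent_N, exponent_Ag,
#'   log_prefactor, se_N, se_Ag, r_squared, n_points, n_dropped.
#' @export
fit_power_law <- function(sweep, method = c("ols", "pls")) {
  method <- match.arg(method)
  keep <- is.finite(sweep$il2_max) & sweep$il2_max > 0
  d <- sweep[keep, , drop = FALSE]
  if (length(unique(d$N_Tcell)) < 2 || length(unique(d$N_Antigen)) < 2)
    stop("rank-deficient design: need >= 2 distinct values on each axis")
  if (nrow(d) < 6) stop("need at least 6 usable points")
  lN <- log10(d$N_Tcell); lA <- log10(d$N_Antigen); ly <- log10(d$il2_max)
  fit <- stats::lm(ly ~ lN + lA)
  co <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))  # exact fits are fine
  if (method == "pls") {
    if (!requireNamespace("mixOmics", quietly = TRUE))
      stop("method = 'pls' requires the mixOmics package")
    X <- cbind(lN = lN, lA = lA)
    pf <- mixOmics::pls(X, ly, ncomp = 2, mode = "regression", scale = FALSE)
    B <- stats::predict(pf, X)$B.hat[, 1, 2]
    co[2:3] <- B
    co[1] <- mean(ly) - sum(B * colMeans(X))
  }
  pred <- co[1] + co[2] * lN + co[3] * lA
  r2 <- 1 - sum((ly - pred)^2) / sum((ly - mean(ly))^2)
  structure(list(exponent_N = unname(co[2]), exponent_Ag = unname(co[3]),
                 log_prefactor = unname(co[1]),
                 se_N = unname(se[2]), se_Ag = unname(se[3]),
                 r_squared = r2, n_points = nrow(d),
                 n_dropped = sum(!keep), method = method),
            class = "il2_powerlaw_fit")
}

#' @export
print.il2_powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "[IL-2]_max ~ N_Tcell^%+.3f (SE %.3f) x N_Antigen^%+.3f (SE %.3f)\n",
    x$exponent_N, x$se_N, x$exponent_Ag, x$se_Ag))
  cat(sprintf("  R^2 = %.4f over %d points (%s)\n", x$r_squared, x$n_points,
              x$method))
  invisible(x)
}

#' Apparent per-cell IL-2 secretion rate over time
#'
#' Estimates the population-apparent secretion rate as the accumulated
#' extracellular IL-2 (in molecules) divided by the cumulative number of
#' producer cell-seconds up to each time point, and reports it as a fold
#' increase over the basal single-cell rate.
#'
#' @param traj an \code{il2_trajectory}.
#' @param basal_rate basal secretion rate, molecules per cell per second
#'   (default 7.5).
#' @param V,N_A culture volume (liters) and Avogadro's number used to convert
#'   concentration to molecules.
#' @return data.frame with time (h), rate (molecules/cell/s) and fold;
#'   time points before the first producer are omitted.
#' @export
secretion_acceleration <- function(traj, basal_rate = 7.5, V = 2e-4,
                                   N_A = 6.02214076e23) {
  dt <- diff(traj$time)
  cum_s <- cumsum(c(0, utils::head(traj$producer_count, -1) * dt)) * 3600
  keep <- cum_s > 0
  rate <- N_A * V * traj$il2_molar[keep] / cum_s[keep]
  data.frame(time = traj$time[keep], rate = rate, fold = rate / basal_rate)
}

#' Paired producer-integral / IL-2 curve with a curvature statistic
#'
#' Pairs the cumulative producer cell-hours with the concurrent IL-2
#' concentration up to the IL-2 peak, and quantifies nonlinearity as the
#' log-log slope of the pairing: a constant per-cell secretion rate gives
#' slope 1; time-accelerating secretion gives slope > 1.
#'
#' @param traj an \code{il2_trajectory}.
#' @param min_frac fraction of the peak cumulative producer time below which
#'   early points are excluded from the slope fit (onset transients).
#' @return list with \code{curve} (data.frame cumulative_producer_time,
#'   il2_molar), \code{exponent}, \code{r_squared}. Empty curve (no IL-2)
#'   gives exponent NA.
#' @export
producer_integral_curve <- function(traj, min_frac = 0.01) {
  dt <- diff(traj$time)
  cum <- cumsum(c(0, utils::head(traj$producer_count, -1) * dt))
  i_max <- which.max(traj$il2_molar)
  keep <- seq_along(cum) <= i_max & cum > 0 & traj$il2_molar > 0
  curve <- data.frame(cumulative_producer_time = cum[keep],
                      il2_molar = traj$il2_molar[keep])
  if (nrow(curve) < 3 || max(traj$il2_molar) <= 0)
    return(list(curve = curve[0, ], exponent = NA_real_,
                r_squared = NA_real_))
  fitrows <- curve$cumulative_producer_time >
    min_frac * max(curve$cumulative_producer_time)
  f <- stats::lm(log10(il2_molar) ~ log10(cumulative_producer_time),
                 data = curve[fitrows, ])
  list(curve = curve, exponent = unname(stats::coef(f)[2]),
       r_squared = suppressWarnings(summary(f)$r.squared))
}

#' Mixed-culture to summed-solo IL-2 ratio distributions
#'
#' For each condition, the ratio of the IL-2 accumulated by the two-clone
#' mixed culture to the sum of the IL-2 accumulated independently by each
#' clone, evaluated at the requested times; the per-time empirical
#' distributions summarize additivity of the production phase and the
#' competition for IL-2 at late times.
#'
#' @param mixes list of \code{il2_trajectory2} (or a single one).
#' @param solos1,solos2 matching lists of single-clone trajectories.
#' @param times evaluation times (h), must lie on the shared output grid.
#' @return data.frame (condition, time, ratio, il2_mix, il2_sum). Conditions
#'   with zero summed solo IL-2 at a time are omitted; the number omitted is
#'   in \code{attr(, "n_dropped")}.
#' @export
mix_ratio_distribution <- function(mixes, solos1, solos2, times) {
  if (inherits(mixes, "il2_trajectory2")) {
    mixes <- list(mixes); solos1 <- list(solos1); solos2 <- list(solos2)
  }
  stopifnot(length(mixes) == length(solos1),
            length(mixes) == length(solos2))
  rows <- list(); dropped <- 0L
  for (k in seq_along(mixes)) {
    m <- mixes[[k]]; s1 <- solos1[[k]]; s2 <- solos2[[k]]
    for (tq in times) {
      i <- match(tq, m$time)
      if (is.na(i)) stop("time ", tq, " not on the trajectory grid")
      denom <- s1$il2_molar[i] + (if (is.null(s2)) 0 else s2$il2_molar[i])
      if (denom <= 0) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = k, time = tq, ratio = m$il2_molar[i] / denom,
        il2_mix = m$il2_molar[i], il2_sum = denom)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = integer(), time = numeric(), ratio = numeric(),
               il2_mix = numeric(), il2_sum = numeric())
  attr(out, "n_dropped") <- dropped
  out
}
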