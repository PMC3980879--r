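#' Configuration for the synthetic flow-cytometry event generator
#'
#' Parameters of the generator that emulates receptor-binned pSTAT5 dose
#' response data: per-cell IL-2Ralpha and IL-2Rbeta fluorescence are
#' log-normal; the per-cell pSTAT5 response to an IL-2 titration is
#' Michaelian with an amplitude that depends on the cell's IL-2Rbeta level
#' (the signaling-limiting chain) and is inhibited by the stimulating antigen
#' dose as \code{1 / (1 + sigma_gen * antigen_dose)}; measurement noise is
#' multiplicative log-normal.
#'
#' @param ra_meanlog,ra_sdlog log-normal location/scale of IL-2Ralpha
#'   fluorescence.
#' @param rb_meanlog,rb_sdlog log-normal location/scale of IL-2Rbeta
#'   fluorescence.
#' @param base pSTAT5 baseline (a.u.).
#' @param amp_max maximal pSTAT5 amplitude (a.u.).
#' @param rb_half IL-2Rbeta fluorescence at half-maximal amplitude: per-cell
#'   amplitude is \code{amp_max * rb / (rb_half + rb)}.
#' @param ec50 IL-2 EC50 (M), antigen-independent.
#' @param sigma_gen antigen inhibition strength (per molar antigen dose).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (default 0.15).
#' @param events_per_condition cells per (antigen, IL-2 dose) stratum.
#' @param il2_doses IL-2 titration (M).
#' @param antigen_doses stimulating antigen doses (M).
#' @param seed integer seed.
#' @return a validated \code{flow_generator_config} list.
#' @export
flow_generator_config <- function(ra_meanlog = log(1500), ra_sdlog = 0.55,
                                  rb_meanlog = log(800), rb_sdlog = 0.5,
                                  base = 100, amp_max = 1800, rb_half = 600,
                                  ec50 = 1e-11, sigma_gen = 3e5,
                                  noise_cv = 0.15,
                                  events_per_condition = 2000,
                                  il2_doses = 10^seq(-13, -8.5, length.out = 12),
                                  antigen_doses = c(1e-8, 1e-7, 1e-6, 1e-5),
                                  seed = 1L) {
  cfg <- list(ra_meanlog = ra_meanlog, ra_sdlog = ra_sdlog,
              rb_meanlog = rb_meanlog, rb_sdlog = rb_sdlog, base = base,
              amp_max = amp_max, rb_half = rb_half, ec50 = ec50,
              sigma_gen = sigma_gen, noise_cv = noise_cv,
              events_per_condition = events_per_condition,
              il2_doses = il2_doses, antigen_doses = antigen_doses,
              seed = as.integer(seed))
  stopifnot(cfg$ra_sdlog > 0, cfg$rb_sdlog > 0, cfg$noise_cv >= 0,
            cfg$events_per_condition >= 1, cfg$amp_max >= 0,
            cfg$rb_half > 0, cfg$ec50 > 0, cfg$sigma_gen >= 0,
            all(cfg$il2_doses >= 0), all(cfg$antigen_doses >= 0))
  structure(cfg, class = "flow_generator_config")
}

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Generate a synthetic flow-like event table
#'
#' Draws single-cell events with known ground truth for CCVA recovery tests.
#' Each stimulation condition draws one receptor population, split across the
#' IL-2 titration wells; pSTAT5 follows the configured receptor-dependent
#' Michaelian response scaled by the antigen inhibition factor.
#'
#' @param cfg a \code{\link{flow_generator_config}}.
#' @return list with \code{events} (EventTable data.frame: condition_id,
#'   antigen_dose, il2_dose, cell_id, il2ra_fi, il2rb_fi, pstat5_fi,
#'   gate_flag) and \code{truth} (per antigen dose: the imposed inhibition
#'   factor). Deterministic under the configured seed.
#' @export
gen_flow_events <- function(cfg) {
  stopifnot(inherits(cfg, "flow_generator_config"))
  with_local_seed(cfg$seed, {
    rows <- list()
    for (ci in seq_along(cfg$antigen_doses)) {
      ag <- cfg$antigen_doses[ci]
      inhib <- 1 / (1 + cfg$sigma_gen * ag)
      # one stained population per stimulation condition, split across the
      # titration wells: receptor levels are shared by all dose strata
      n <- cfg$events_per_condition
      ra <- stats::rlnorm(n, cfg$ra_meanlog, cfg$ra_sdlog)
      rb <- stats::rlnorm(n, cfg$rb_meanlog, cfg$rb_sdlog)
      amp <- cfg$amp_max * rb / (cfg$rb_half + rb)
      for (dose in cfg$il2_doses) {
        resp <- cfg$base + amp * inhib * dose / (cfg$ec50 + dose)
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = paste0("ag_", format(ag, scientific = TRUE)),
          antigen_dose = ag, il2_dose = dose, cell_id = seq_len(n),
          il2ra_fi = ra, il2rb_fi = rb,
          pstat5_fi = resp * lnorm_noise(n, cfg$noise_cv),
          gate_flag = 1L)
      }
    }
    events <- do.call(rbind, rows)
    truth <- data.frame(
      antigen_dose = cfg$antigen_doses,
      inhibition_factor = 1 / (1 + cfg$sigma_gen * cfg$antigen_doses))
    list(events = events, truth = truth)
  })
}

#' Resample a trajectory as a noisy assay-like time series
#'
#' Emulates supernatant sampling: the trajectory is subsampled on a coarse
#' grid (default every 4 h), multiplicative log-normal noise with the given
#' coefficient of variation is applied, and values below the limit of
#' detection are censored to \code{NA}.
#'
#' @param traj an \code{il2_trajectory} (or list with time, il2_molar).
#' @param cv noise coefficient of variation (>= 0).
#' @param lod limit of detection (M, >= 0).
#' @param seed integer seed.
#' @param dt sampling interval (h, default 4).
#' @return data.frame with time and il2_molar (NA where censored).
#' @export
gen_noisy_timeseries <- function(traj, cv, lod = 0, seed = 1L, dt = 4) {
  stopifnot(cv >= 0, lod >= 0)
  tq <- seq(min(traj$time), max(traj$time), by = dt)
  idx <- match(tq, traj$time)
  if (anyNA(idx)) {
    vals <- stats::approx(traj$time, traj$il2_molar, xout = tq)$y
  } else vals <- traj$il2_molar[idx]
  noisy <- with_local_seed(seed, vals * lnorm_noise(length(vals), cv))
  noisy[noisy < lod] <- NA_real_
  data.frame(time = tq, il2_molar = noisy)
}

#' Generate calibration and sample series for the antigenicity workflow
#'
#' Runs the cohort model at each calibration antigen dose and at each hidden
#' sample load, records (pSTAT5, [IL-2], IL-2Ralpha) on a coarse sampling
#' grid over the production phase, and applies multiplicative noise. The
#' hidden loads are returned separately so recovery can be scored without
#' the analysis stage ever reading them.
#'
#' @param truth_doses calibration antigen-molecule doses (span >= 2 decades).
#' @param sample_loads hidden sample antigen loads (molecules).
#' @param noise_cv multiplicative noise CV applied to all three readouts.
#' @param seed integer seed.
#' @param p model parameters (default \code{il2_params()}).
#' @param N_Tcell T cells per culture (default 4e4, the assay's input).
#' @param t_max last sampling time (h, default 52), dt sampling interval (h).
#' @param dt sampling interval (h, default 8).
#' @return list with \code{calibration} (series_id, antigen_dose, time,
#'   pstat5, il2_molar, il2ra), \code{samples} (series_id, time, ...), and
#'   \code{truth} (series_id, antigen_load).
#' @export
gen_calibration_and_samples <- function(truth_doses, sample_loads,
                                        noise_cv = 0, seed = 1L,
                                        p = il2_params(), N_Tcell = 4e4,
                                        t_max = 52, dt = 8) {
  if (diff(range(log10(truth_doses))) < 2)
    stop("calibration doses must span >= 2 decades")
  # one activation-time draw shared by every series: all co-cultures follow
  # the same assay protocol, so conditions differ only in antigen load
  act_seed <- derive_seed(seed, 1L)
  series <- function(ag, sid, noise_seed) {
    tr <- run_cohort(p, N_Tcell, ag, t_end = t_max, seed = act_seed)
    tq <- seq(0, t_max, by = dt)
    i <- match(tq, tr$time)
    n <- length(i)
    with_local_seed(noise_seed, data.frame(
      series_id = sid, time = tq,
      pstat5 = rowMeans(tr$p_stat5)[i] * lnorm_noise(n, noise_cv),
      il2_molar = tr$il2_molar[i] * lnorm_noise(n, noise_cv),
      il2ra = rowMeans(tr$n_IL2Ra)[i] * lnorm_noise(n, noise_cv)))
  }
  cal <- do.call(rbind, lapply(seq_along(truth_doses), function(k) {
    d <- series(truth_doses[k], paste0("cal_", k), derive_seed(seed, 10 + k))
    d$antigen_dose <- truth_doses[k]
    d
  }))
  smp <- do.call(rbind, lapply(seq_along(sample_loads), function(k) {
    series(sample_loads[k], paste0("sample_", k), derive_seed(seed, 100 + k))
  }))
  list(calibration = cal, samples = smp,
       truth = data.frame(series_id = paste0("sample_", seq_along(sample_loads)),
                          antigen_load = sample_loads))
}
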