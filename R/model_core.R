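#' Equilibrium complex count for a bimolecular association
#'
#' Number of complexes at thermodynamic equilibrium for X + Y <-> XY given
#' total abundances and the equilibrium constant, i.e. the physical root of
#' the mass-action quadratic (x - C)(y - C) = K C. Used for both pMHC-TCR
#' engagement and IL-2Ralpha / IL-2Rbeta-gamma receptor pre-assembly.
#'
#' The naive root 0.5 (x + y + K - sqrt((x+y+K)^2 - 4xy)) loses precision when
#' x y << (x+y+K)^2; the algebraically equivalent form 2xy / (x+y+K + sqrt(.))
#' is used instead, which is stable for all non-negative inputs.
#'
#' @param x_total,y_total total molecule counts of the two partners.
#' @param K equilibrium constant, molecule-count units.
#' @return complex count, bounded by \code{min(x_total, y_total)}. Vectorized.
#' @export
#' @examples
#' equilibrium_complex(500, 800, 0)   # K = 0 gives min(x, y)
equilibrium_complex <- function(x_total, y_total, K) {
  if (any(x_total < 0) || any(y_total < 0) || any(K < 0))
    stop("equilibrium_complex: all arguments must be non-negative")
  b <- x_total + y_total + K
  disc <- pmax(b * b - 4 * x_total * y_total, 0)
  denom <- b + sqrt(disc)
  ifelse(denom > 0, 2 * x_total * y_total / denom, 0)
}

#' Heaviside step indicator
#'
#' All-or-none threshold used throughout the model: activation, receptor
#' production and IL-2 secretion switch on when their input reaches the
#' threshold (boundary included).
#'
#' @param x input value(s).
#' @param threshold threshold value.
#' @return 0 where \code{x < threshold}, 1 where \code{x >= threshold}.
#' @export
step_indicator <- function(x, threshold) {
  as.numeric(x >= threshold)
}

#' Number of antigen-engaged TCR on one cell
#'
#' Zero before the cell's activation time; afterwards the equilibrium complex
#' count between the cell's TCR pool and an equal share of the clone's free
#' antigen among currently active cells.
#'
#' @param t time (h).
#' @param cell_index index of the cell (1-based).
#' @param state cohort state list with fields \code{n_pMHC} and \code{t_act}.
#' @param p an \code{\link{il2_params}} object.
#' @return engaged-TCR count for that cell.
#' @export
engaged_tcr <- function(t, cell_index, state, p) {
  t_act <- state$t_act
  if (t < t_act[cell_index]) return(0)
  n_act <- sum(step_indicator(t, t_act))
  if (n_act == 0) return(0)
  equilibrium_complex(p$n_TCR_0, max(state$n_pMHC, 0) / n_act, p$K_TCR_pMHC)
}

#' Fraction of phosphorylated STAT5 in one cell
#'
#' Saturating response to the bound IL-2/IL-2R complex count, multiplied by
#' TCR-mediated inhibition 1 / (1 + sigma_TCR_inh * engaged TCR). The
#' inhibition factor is dropped when cross-talk is disabled; under JAK
#' blockade the fraction is identically zero.
#'
#' @param n_cplx bound IL-2/IL-2R complex count (>= 0).
#' @param n_engagedTCR engaged-TCR count (>= 0).
#' @param p an \code{\link{il2_params}} object.
#' @return pSTAT5 fraction in [0, 1]. Vectorized over the first two arguments.
#' @export
pstat5_fraction <- function(n_cplx, n_engagedTCR, p) {
  if (any(n_cplx < 0) || any(n_engagedTCR < 0))
    stop("pstat5_fraction: inputs must be non-negative")
  if (p$jak_blocked) return(0 * n_cplx)
  base <- n_cplx / (p$K_IL2_pSTAT5 + n_cplx)
  xtalk <- crosstalk_on(p)
  inh <- if (xtalk) 1 / (1 + p$sigma_TCR_inh * n_engagedTCR) else 1
  base * inh
}

# classical_mode forces both novel regulatory elements off
crosstalk_on <- function(p) p$crosstalk_enabled && !p$classical_mode
boost_on     <- function(p) p$boost_enabled && !p$classical_mode

#' Per-cell IL-2 secretion rate
#'
#' All-or-none secretion gated on engaged TCR discounted by pSTAT5-mediated
#' inhibition; the rate is the basal TCR-dependent rate plus the
#' Boost-dependent term proportional to the cell's activated-Boost fraction.
#'
#' @param cell_index index of the cell.
#' @param state cohort state list with fields \code{n_engagedTCR},
#'   \code{p_stat5} and \code{n_boost} (vectors over cells).
#' @param p an \code{\link{il2_params}} object.
#' @return secretion rate in molecules per hour.
#' @export
il2_secretion_rate <- function(cell_index, state, p) {
  eng <- state$n_engagedTCR[cell_index]
  p5 <- state$p_stat5[cell_index]
  fb <- if (boost_on(p)) state$n_boost[cell_index] / p$n_Boost_total else 0
  gate <- step_indicator(eng / (1 + p$sigma_pSTAT5_inh * p5), p$tau_activation)
  kb <- if (boost_on(p)) p$k_Boost_IL2 else 0
  (p$k_IL2_basal + kb * fb) * gate
}

#' Reference right-hand side of the cohort ODE system (single clone)
#'
#' Pure-R implementation of the model derivatives, the contract surface of the
#' model core. Integration uses an equivalent compiled version
#' (\code{\link{run_cohort}}); tests assert agreement between the two.
#'
#' The state vector packs, in order: free pMHC (molecules in the scaled cohort
#' volume V * n_sim_cells / N_Tcell), extracellular IL-2 (molecules in the
#' same scaled volume), then per-cell IL-2Ralpha, IL-2Rbeta/gamma, bound
#' IL-2/IL-2R complex and activated Boost (molecule counts).
#'
#' @param t time (h).
#' @param state_vector packed state, length 2 + 4 * n_sim_cells.
#' @param p an \code{\link{il2_params}} object.
#' @param N_Tcell number of T cells represented by the cohort.
#' @param t_act activation times (h), length n_sim_cells.
#' @return list whose first element is the derivative vector (deSolve
#'   convention), followed by per-cell pSTAT5 and secretion-gate vectors.
#' @export
model_rhs <- function(t, state_vector, p, N_Tcell, t_act) {
  n <- p$n_sim_cells
  stopifnot(length(state_vector) == 2 + 4 * n, length(t_act) == n)
  bad <- !is.finite(state_vector)
  if (any(bad))
    stop("model_rhs: non-finite state entry at index ", which(bad)[1])
  neg <- state_vector < -1e-6 * max(1, abs(state_vector))
  if (any(neg))
    stop("model_rhs: negative state entry at index ", which(neg)[1])
  y <- pmax(state_vector, 0)

  n_pMHC <- y[1]; n_IL2 <- y[2]
  Ra   <- y[2 + seq_len(n)]
  Rb   <- y[2 + n + seq_len(n)]
  cplx <- y[2 + 2 * n + seq_len(n)]
  bst  <- pmin(y[2 + 3 * n + seq_len(n)], p$n_Boost_total)

  S <- N_Tcell / n                 # cells represented per simulated cell
  V_scaled <- p$V / S              # cohort volume (liters)
  il2_molar <- n_IL2 / (V_scaled * p$N_A)

  on <- t >= t_act
  n_act <- sum(on)
  eng_active <- if (n_act > 0)
    equilibrium_complex(p$n_TCR_0, n_pMHC / n_act, p$K_TCR_pMHC) else 0
  eng <- ifelse(on, eng_active, 0)

  act <- step_indicator(eng, p$tau_activation)
  preR <- equilibrium_complex(Ra, Rb, p$K_IL2R_pre)
  p5 <- pstat5_fraction(cplx, eng, p)

  dRa <- p$k_receptor_deg *
    (p$n_TCR_IL2Ra_max * act + p$n_pSTAT5_IL2Ra_max * p5 - Ra)
  dRb <- p$k_receptor_deg *
    (p$n_IL2Rb_0 + (p$n_IL2Rb_max - p$n_IL2Rb_0) * act - Rb)

  bind <- p$k_bind * il2_molar * (preR - cplx)   # molecules / h / cell
  dcplx <- bind - p$k_endo * cplx

  fb <- bst / p$n_Boost_total
  k_tb <- if (boost_on(p)) p$k_TCR_Boost else 0
  k_bb <- if (boost_on(p)) p$k_Boost_Boost else 0
  dbst <- (k_tb * eng + k_bb * bst) * (1 - fb)

  gate <- step_indicator(eng / (1 + p$sigma_pSTAT5_inh * p5),
                         p$tau_activation)
  kb <- if (boost_on(p)) p$k_Boost_IL2 else 0
  secr <- (p$k_IL2_basal + kb * fb) * gate

  dpMHC <- -p$k_ag_consume * sum(eng)
  if (n_pMHC <= 0 && dpMHC < 0) dpMHC <- 0
  dIL2 <- sum(secr - bind)

  list(c(dpMHC, dIL2, dRa, dRb, dcplx, dbst),
       p_stat5 = p5, producing = gate, n_engagedTCR = eng)
}
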