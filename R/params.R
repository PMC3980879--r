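#' Model parameters for the IL-2 cohort model
#'
#' Constructs the full parameter set of the cohort ODE model of antigen-driven
#' IL-2 production, consumption and signaling. Defaults reproduce the published
#' parameterization of the pathway: TCR-pMHC engagement by mass-action
#' equilibrium, threshold (all-or-none) activation, two-mode IL-2Ralpha
#' synthesis, IL-2Rbeta step-up on activation, fast binding and endocytosis of
#' the full IL-2/IL-2R complex, TCR-mediated inhibition of STAT5
#' phosphorylation, pSTAT5-mediated shutdown of secretion, and an autocatalytic
#' "Boost" variable that accelerates per-cell secretion up to 30-fold.
#'
#' @param ... named overrides of any default field (see Details).
#'
#' @details Fields (units in parentheses):
#' \describe{
#'   \item{K_TCR_pMHC}{equilibrium constant of pMHC-TCR complex formation
#'     (molecules), default 30000.}
#'   \item{K_IL2R_pre}{equilibrium constant of IL-2Ralpha / IL-2Rbeta-gamma
#'     pre-assembly (molecules), default 2700.}
#'   \item{sigma_TCR_inh}{efficiency of TCR inhibition of STAT5
#'     phosphorylation (per engaged TCR), default 0.01.}
#'   \item{K_IL2_pSTAT5}{half-saturation of pSTAT5 versus bound IL-2/IL-2R
#'     complex count (molecules), default 1e4.}
#'   \item{k_ag_consume}{antigen consumption rate (1/h), default ln(2)/3.5.}
#'   \item{tau_activation}{threshold number of engaged TCR to start
#'     activation, default 1. Also used for the receptor- and
#'     secretion-production thresholds, which share this value.}
#'   \item{n_TCR_IL2Ra_max}{TCR-driven IL-2Ralpha plateau (molecules),
#'     default 1000.}
#'   \item{k_receptor_deg}{receptor turnover rate (1/h), default ln(2)/5.}
#'   \item{n_pSTAT5_IL2Ra_max}{pSTAT5-driven IL-2Ralpha plateau (molecules),
#'     default 2e6.}
#'   \item{n_IL2Rb_0, n_IL2Rb_max}{basal and activated IL-2Rbeta abundance
#'     (molecules), defaults 1e3 and 1e4.}
#'   \item{k_bind}{IL-2 association rate to the preformed receptor
#'     (per molar per hour), default 1e11.}
#'   \item{k_endo}{internalization rate of the full complex (1/h),
#'     default ln(2)/0.25.}
#'   \item{k_IL2_basal}{TCR-dependent IL-2 secretion rate
#'     (molecules/h/cell), default 7.5*3600.}
#'   \item{sigma_pSTAT5_inh}{pSTAT5-dependent inhibition of IL-2 production
#'     (dimensionless), default 3e5.}
#'   \item{n_Boost_total}{total Boost molecules per cell, default 1e5.}
#'   \item{k_TCR_Boost}{TCR-dependent Boost activation rate, default 1e-3.}
#'   \item{k_Boost_Boost}{autocatalytic Boost activation rate (1/h),
#'     default 0.3.}
#'   \item{k_Boost_IL2}{Boost-dependent secretion rate (molecules/h/cell),
#'     default 30 * k_IL2_basal.}
#'   \item{n_TCR_0}{TCR per cell, default 3e4.}
#'   \item{V}{culture volume (liters), default 2e-4.}
#'   \item{N_A}{Avogadro's number.}
#'   \item{activation_window}{interval (h) for uniformly distributed
#'     activation delays, default c(10, 60).}
#'   \item{crosstalk_enabled, boost_enabled, jak_blocked, classical_mode}{
#'     logical toggles selecting model variants. \code{classical_mode = TRUE}
#'     disables cross-talk and boost simultaneously.}
#'   \item{n_sim_cells}{number of representative cells simulated, default 50.}
#'   \item{rng_seed}{integer seed for activation-time sampling, default 1.}
#'   \item{rtol, atol}{solver relative/absolute tolerances, defaults 1e-6 and
#'     1e-3 (molecules).}
#'   \item{dt_out}{output grid spacing (h), default 0.5.}
#' }
#'
#' @return an object of class \code{il2_params} (a validated named list).
#' @export
#' @examples
#' p <- il2_params()
#' p$k_Boost_IL2 / p$k_IL2_basal  # 30
il2_params <- function(...) {
  p <- il2_default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
}

il2_default_params <- function() {
  k_IL2_basal <- 7.5 * 3600
  list(
    K_TCR_pMHC        = 30000,
    K_IL2R_pre        = 2700,
    sigma_TCR_inh     = 0.01,
    K_IL2_pSTAT5      = 1e4,
    k_ag_consume      = log(2) / 3.5,
    tau_activation    = 1,
    n_TCR_IL2Ra_max   = 1000,
    k_receptor_deg    = log(2) / 5,
    n_pSTAT5_IL2Ra_max = 2e6,
    n_IL2Rb_0         = 1e3,
    n_IL2Rb_max       = 1e4,
    k_bind            = 1e11,
    k_endo            = log(2) / 0.25,
    k_IL2_basal       = k_IL2_basal,
    sigma_pSTAT5_inh  = 3e5,
    n_Boost_total     = 1e5,
    k_TCR_Boost       = 1e-3,
    k_Boost_Boost     = 0.3,
    k_Boost_IL2       = 30 * k_IL2_basal,
    n_TCR_0           = 3e4,
    V                 = 2e-4,
    N_A               = 6.02214076e23,
    activation_window = c(10, 60),
    crosstalk_enabled = TRUE,
    boost_enabled     = TRUE,
    jak_blocked       = FALSE,
    classical_mode    = FALSE,
    n_sim_cells       = 50L,
    rng_seed          = 1L,
    rtol              = 1e-6,
    atol              = 1e-3,
    dt_out            = 0.5
  )
}

positive_fields <- c(
  "K_TCR_pMHC", "K_IL2R_pre", "sigma_TCR_inh", "K_IL2_pSTAT5", "k_ag_consume",
  "tau_activation", "n_TCR_IL2Ra_max", "k_receptor_deg", "n_pSTAT5_IL2Ra_max",
  "n_IL2Rb_0", "n_IL2Rb_max", "k_bind", "k_endo", "k_IL2_basal",
  "sigma_pSTAT5_inh", "n_Boost_total", "k_TCR_Boost", "k_Boost_Boost",
  "k_Boost_IL2", "n_TCR_0", "V", "N_A", "rtol", "atol", "dt_out"
)

toggle_fields <- c("crosstalk_enabled", "boost_enabled", "jak_blocked",
                   "classical_mode")

validate_params <- function(p) {
  for (f in positive_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single strictly positive number")
  }
  for (f in toggle_fields) {
    v <- p[[f]]
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop("parameter '", f, "' must be TRUE or FALSE")
  }
  w <- p$activation_window
  if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)) ||
      w[1] < 0 || w[1] >= w[2])
    stop("'activation_window' must be c(lo, hi) with 0 <= lo < hi")
  n <- p$n_sim_cells
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("'n_sim_cells' must be a positive integer")
  p$n_sim_cells <- as.integer(n)
  s <- p$rng_seed
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s != round(s))
    stop("'rng_seed' must be a non-negative integer")
  p$rng_seed <- as.integer(s)
  structure(p, class = "il2_params")
}

#' Load model parameters from a YAML or JSON config file
#'
#' Reads a flat key/value file whose keys are \code{\link{il2_params}} field
#' names. Missing keys are filled from the defaults; unknown keys are an
#' error. An empty file yields the full default parameter set.
#'
#' @param path path to a YAML (\code{.yml}/\code{.yaml}) or JSON file.
#' @return an \code{il2_params} object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must parse to a key/value mapping")
  do.call(il2_params, vals)
}

#' Resolve variant toggles by name
#'
#' Maps a variant label to the corresponding parameter toggles:
#' \code{"full"} (cross-talk and boost on), \code{"classical"} (both off),
#' \code{"nocrosstalk"}, \code{"noboost"}, and \code{"jak"} (pSTAT5 forced
#' to zero).
#'
#' @param p an \code{il2_params} object.
#' @param variant one of \code{"full"}, \code{"classical"},
#'   \code{"nocrosstalk"}, \code{"noboost"}, \code{"jak"}.
#' @return \code{p} with toggles set.
#' @export
set_variant <- function(p, variant = c("full", "classical", "nocrosstalk",
                                       "noboost", "jak")) {
  variant <- match.arg(variant)
  p$crosstalk_enabled <- variant %in% c("full", "noboost", "jak")
  p$boost_enabled     <- variant %in% c("full", "nocrosstalk", "jak")
  p$jak_blocked       <- variant == "jak"
  p$classical_mode    <- variant == "classical"
  validate_params(p)
}

#' @export
print.il2_params <- function(x, ...) {
  cat("IL-2 cohort model parameters\n")
  cat(sprintf("  variant toggles: crosstalk=%s boost=%s jak_blocked=%s classical=%s\n",
              x$crosstalk_enabled, x$boost_enabled, x$jak_blocked,
              x$classical_mode))
  cat(sprintf("  n_sim_cells=%d, activation window [%g, %g] h\n",
              x$n_sim_cells, x$activation_window[1], x$activation_window[2]))
  scalars <- setdiff(names(x), c("activation_window", toggle_fields))
  for (f in scalars) cat(sprintf("  %-20s %g\n", f, x[[f]]))
  invisible(x)
}
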