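#' Fit the SlopeXtalk statistic
#'
#' During the IL-2 production phase, pSTAT5 grows linearly with the product
#' of IL-2 concentration and IL-2Ralpha abundance; the slope of that line
#' (SlopeXtalk) falls with the antigen load driving the culture, because TCR
#' signaling inhibits STAT5 phosphorylation. Fits
#' \code{pstat5 = slope_xtalk * (il2 * il2ra) + background} by ordinary
#' least squares over the production-phase window.
#'
#' @param times time points (h).
#' @param pstat5 pSTAT5 readout per time point (a.u.).
#' @param il2 IL-2 concentration per time point (M).
#' @param il2ra IL-2Ralpha abundance per time point (a.u. or molecules).
#' @param t_max production-phase cutoff in hours (default 52); points beyond
#'   it are excluded.
#' @param pre_peak if TRUE (default) also exclude points after the IL-2
#'   series' maximum: pSTAT5 tracks the product linearly while IL-2
#'   accumulates, and hooks away from the line once consumption dominates.
#' @return list: slope_xtalk, background, se_slope, se_background, n_points.
#' @export
fit_slope_xtalk <- function(times, pstat5, il2, il2ra, t_max = 52,
                            pre_peak = TRUE) {
  keep <- times <= t_max
  if (pre_peak && any(is.finite(il2)))
    keep <- keep & seq_along(times) <= which.max(il2)
  x <- il2[keep] * il2ra[keep]
  y <- pstat5[keep]
  if (length(x) < 3) stop("need >= 3 production-phase time points")
  if (stats::sd(x) == 0)
    stop("degenerate predictor: il2 * il2ra has zero variance")
  f <- stats::lm(y ~ x)
  co <- stats::coef(f)
  se <- sqrt(diag(suppressWarnings(stats::vcov(f))))  # exact fits are fine
  list(slope_xtalk = unname(co[2]), background = unname(co[1]),
       se_slope = unname(se[2]), se_background = unname(se[1]),
       n_points = sum(keep))
}

#' Build the antigen-dose calibration curve from SlopeXtalk measurements
#'
#' The calibration series must span at least two decades of antigen and be
#' strictly monotone (slope_xtalk decreasing in dose); a non-monotone series
#' is rejected naming the violating pair. Two mappings are stored: the global
#' inverse-proportionality fit (log antigen linear in log slope, used for
#' diagnostics and for extrapolation beyond the calibrated range) and the
#' piecewise log-log interpolant through the calibration points, which is the
#' inverse mapping applied within the calibrated range (so a sample whose
#' slope equals a calibration point's recovers exactly that point's dose).
#'
#' @param antigen_dose calibration doses (>= 4, positive).
#' @param slope_xtalk fitted SlopeXtalk per dose (positive).
#' @return an \code{il2_calibration} object with the fitted mapping,
#'   residual diagnostics, and the calibrated slope range.
#' @export
build_calibration <- function(antigen_dose, slope_xtalk) {
  if (length(antigen_dose) != length(slope_xtalk))
    stop("antigen_dose and slope_xtalk must have equal length")
  if (length(antigen_dose) < 4) stop("need >= 4 calibration doses")
  if (any(antigen_dose <= 0) || any(slope_xtalk <= 0))
    stop("doses and slopes must be positive")
  if (diff(range(log10(antigen_dose))) < 2)
    stop("calibration doses must span >= 2 decades")
  o <- order(antigen_dose)
  ad <- antigen_dose[o]; sx <- slope_xtalk[o]
  if (anyDuplicated(ad)) stop("duplicate calibration doses")
  bad <- which(diff(sx) >= 0)
  if (length(bad))
    stop(sprintf(
      "calibration rejected: slope_xtalk not decreasing between doses %g and %g",
      ad[bad[1]], ad[bad[1] + 1]))
  f <- stats::lm(log10(ad) ~ log10(sx))
  structure(list(antigen_dose = ad, slope_xtalk = sx,
                 intercept = unname(stats::coef(f)[1]),
                 slope = unname(stats::coef(f)[2]),
                 residuals = unname(stats::resid(f)),
                 r_squared = suppressWarnings(summary(f)$r.squared),
                 slope_range = range(sx)),
            class = "il2_calibration")
}

#' @export
print.il2_calibration <- function(x, ...) {
  cat(sprintf(
    "SlopeXtalk calibration: log10(antigen) = %.3f %+.3f log10(slope)\n",
    x$intercept, x$slope))
  cat(sprintf("  %d doses [%g, %g], R^2 = %.4f, max |log10 resid| = %.3f\n",
              length(x$antigen_dose), min(x$antigen_dose),
              max(x$antigen_dose), x$r_squared, max(abs(x$residuals))))
  invisible(x)
}

#' Back-calculate effective antigenicity from a sample's SlopeXtalk
#'
#' Applies the inverse calibration mapping. Samples whose slope falls outside
#' the calibrated range are still mapped but flagged as extrapolated.
#'
#' @param sample_slope SlopeXtalk value(s) of the sample(s), positive.
#' @param cal an \code{il2_calibration}.
#' @return data.frame with \code{slope_xtalk}, \code{antigenicity} and
#'   logical \code{extrapolated}.
#' @export
back_calculate_antigenicity <- function(sample_slope, cal) {
  stopifnot(inherits(cal, "il2_calibration"))
  if (any(!is.finite(sample_slope)) || any(sample_slope <= 0))
    stop("sample slopes must be positive")
  ls <- log10(sample_slope)
  # within the calibrated range: interpolate through the calibration points;
  # beyond it: extend with the global inverse-proportionality line
  o <- order(cal$slope_xtalk)
  inner <- stats::approx(log10(cal$slope_xtalk)[o],
                         log10(cal$antigen_dose)[o], xout = ls,
                         rule = 1)$y
  outer <- cal$intercept + cal$slope * ls
  extrap <- sample_slope < cal$slope_range[1] |
    sample_slope > cal$slope_range[2]
  ag <- 10^(ifelse(extrap, outer, inner))
  data.frame(slope_xtalk = sample_slope, antigenicity = ag,
             extrapolated = extrap)
}

#' Fit the two-clone pSTAT5/IL-2Ralpha ratio scaling with antigen doses
#'
#' In a two-clone culture the shared IL-2 cancels from the ratio
#' \code{(pSTAT5_2 * IL2Ra_1) / (pSTAT5_1 * IL2Ra_2)}, leaving a pure
#' function of the two antigen doses. Fits the power-law form
#' \code{ratio = C * Ag1^a1 * Ag2^a2} by nonlinear least squares and reports
#' exponents with 95% confidence intervals.
#'
#' @param conditions data.frame with columns \code{pstat5_1}, \code{pstat5_2},
#'   \code{il2ra_1}, \code{il2ra_2}, \code{Ag1}, \code{Ag2} (>= 4 rows with
#'   distinct dose pairs).
#' @return an \code{il2_two_clone_fit}: exponent_a1, exponent_a2,
#'   ci_half_width_a1/a2 (95%), chi_squared, n_conditions, n_dropped, and the
#'   per-condition ratios.
#' @export
two_clone_ratio_fit <- function(conditions) {
  need <- c("pstat5_1", "pstat5_2", "il2ra_1", "il2ra_2", "Ag1", "Ag2")
  if (!all(need %in% names(conditions)))
    stop("conditions must have columns: ", paste(need, collapse = ", "))
  denom <- conditions$pstat5_1 * conditions$il2ra_2
  keep <- is.finite(denom) & denom > 0 &
    conditions$pstat5_2 * conditions$il2ra_1 > 0
  dropped <- sum(!keep)
  d <- conditions[keep, , drop = FALSE]
  if (nrow(unique(d[c("Ag1", "Ag2")])) < 4)
    stop("need >= 4 conditions with distinct (Ag1, Ag2) pairs")
  d$ratio <- (d$pstat5_2 * d$il2ra_1) / (d$pstat5_1 * d$il2ra_2)
  lf <- stats::lm(log(ratio) ~ log(Ag1) + log(Ag2), data = d)
  start <- list(logC = stats::coef(lf)[[1]], a1 = stats::coef(lf)[[2]],
                a2 = stats::coef(lf)[[3]])
  nf <- minpack.lm::nlsLM(ratio ~ exp(logC) * Ag1^a1 * Ag2^a2, data = d,
                          start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(nf)
  se <- sqrt(diag(stats::vcov(nf)))
  tq <- stats::qt(0.975, df = nrow(d) - 3)
  structure(list(exponent_a1 = unname(co["a1"]),
                 exponent_a2 = unname(co["a2"]),
                 ci_half_width_a1 = unname(tq * se["a1"]),
                 ci_half_width_a2 = unname(tq * se["a2"]),
                 chi_squared = sum(stats::resid(nf)^2),
                 n_conditions = nrow(d), n_dropped = dropped,
                 ratios = d[c("Ag1", "Ag2", "ratio")]),
            class = "il2_two_clone_fit")
}

#' @export
print.il2_two_clone_fit <- function(x, ...) {
  cat(sprintf(
    "two-clone ratio ~ Ag1^%+.2f (+-%.2f) * Ag2^%+.2f (+-%.2f), n = %d\n",
    x$exponent_a1, x$ci_half_width_a1, x$exponent_a2, x$ci_half_width_a2,
    x$n_conditions))
  invisible(x)
}
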