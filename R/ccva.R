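#' Bin single-cell events by IL-2 receptor abundance
#'
#' Cell-to-cell variability analysis starts by parsing gated single-cell
#' events into a 2-D grid of bins over IL-2Ralpha and IL-2Rbeta fluorescence,
#' log-spaced over the pooled data range so that the same bin addresses the
#' same receptor stratum in every stimulation condition.
#'
#' @param events EventTable data frame with columns \code{condition_id},
#'   \code{antigen_dose}, \code{il2_dose}, \code{il2ra_fi}, \code{il2rb_fi},
#'   \code{pstat5_fi} and optional \code{gate_flag} (nonzero = keep).
#' @param n_bins_per_axis number of bins per receptor axis (>= 2, default 8).
#' @param min_events minimum events a bin must hold in every IL-2-dose
#'   stratum of a condition for that (bin, condition) to be retained.
#' @return the events with \code{ra_bin}, \code{rb_bin}, \code{bin_id} and
#'   logical \code{retained} columns; bin edges are attached as attributes
#'   \code{ra_edges}, \code{rb_edges}.
#' @export
bin_events <- function(events, n_bins_per_axis = 8, min_events = 20) {
  if (!nrow(events)) stop("empty event table")
  if (n_bins_per_axis < 2) stop("n_bins_per_axis must be >= 2")
  if (!is.null(events$gate_flag)) events <- events[events$gate_flag != 0, ]
  if (!nrow(events)) stop("no gated events")
  if (any(events$il2ra_fi <= 0) || any(events$il2rb_fi <= 0))
    stop("gated fluorescence values must be positive")
  edges <- function(x) {
    r <- range(log10(x))
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5) * 1e-6
    e <- seq(r[1], r[2], length.out = n_bins_per_axis + 1)
    e[1] <- e[1] - 1e-9; e[length(e)] <- e[length(e)] + 1e-9
    e
  }
  ra_e <- edges(events$il2ra_fi); rb_e <- edges(events$il2rb_fi)
  events$ra_bin <- cut(log10(events$il2ra_fi), ra_e, labels = FALSE)
  events$rb_bin <- cut(log10(events$il2rb_fi), rb_e, labels = FALSE)
  events$bin_id <- paste0(events$ra_bin, "_", events$rb_bin)

  # a (condition, bin) is retained only if every IL-2 dose stratum is filled
  n_dose <- length(unique(events$il2_dose))
  tab <- stats::aggregate(list(n = events$pstat5_fi),
                          by = list(condition_id = events$condition_id,
                                    bin_id = events$bin_id,
                                    il2_dose = events$il2_dose), length)
  ok <- stats::aggregate(list(full = tab$n >= min_events,
                              strata = rep(1L, nrow(tab))),
                         by = list(condition_id = tab$condition_id,
                                   bin_id = tab$bin_id),
                         sum)
  ok$keep <- ok$full == ok$strata & ok$strata == n_dose
  key <- paste(events$condition_id, events$bin_id)
  events$retained <- ok$keep[match(key, paste(ok$condition_id, ok$bin_id))]
  attr(events, "ra_edges") <- ra_e
  attr(events, "rb_edges") <- rb_e
  events
}

#' Fit a three-parameter Hill dose response
#'
#' Least-squares fit of \code{response = base + amplitude * dose^n /
#' (ec50^n + dose^n)} with the Hill coefficient fixed (default 1, the
#' near-Michaelian IL-2 receptor regime), estimating base, amplitude and
#' EC50.
#'
#' @param doses dose values (>= 4 points, molar).
#' @param responses responses (same length, a.u.).
#' @param hill_n fixed Hill coefficient (default 1).
#' @return an \code{il2_hill_fit} list: base, amplitude, ec50, fit_ok,
#'   degenerate (flat-response flag), residual_norm.
#' @export
fit_hill <- function(doses, responses, hill_n = 1) {
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  if (length(doses) < 4)
    stop("need at least 4 dose points for a 3-parameter fit")
  span <- diff(range(responses))
  if (span <= max(1e-12, 1e-9 * max(abs(responses)))) {
    return(structure(list(base = mean(responses), amplitude = 0,
                          ec50 = stats::median(doses), fit_ok = TRUE,
                          degenerate = TRUE, residual_norm = 0),
                     class = "il2_hill_fit"))
  }
  d <- data.frame(x = doses, y = responses)
  start <- list(base = min(responses), amplitude = span,
                ec50 = stats::median(doses[doses > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ base + amplitude * x^hill_n / (ec50^hill_n + x^hill_n),
      data = d, start = start,
      lower = c(base = 0, amplitude = 0, ec50 = min(doses[doses > 0]) / 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(base = NA_real_, amplitude = NA_real_,
                          ec50 = NA_real_, fit_ok = FALSE, degenerate = FALSE,
                          residual_norm = NA_real_), class = "il2_hill_fit"))
  }
  co <- stats::coef(fit)
  dr <- range(doses[doses > 0])
  ok <- co[["ec50"]] >= dr[1] / 100 && co[["ec50"]] <= dr[2] * 100
  structure(list(base = co[["base"]], amplitude = co[["amplitude"]],
                 ec50 = co[["ec50"]], fit_ok = ok, degenerate = FALSE,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "il2_hill_fit")
}

# geometric mean (the GMFI convention for fluorescence summaries)
gmfi <- function(x) exp(mean(log(pmax(x, .Machine$double.xmin))))

#' Per-bin Hill fits of pSTAT5 against IL-2 dose
#'
#' For every retained (condition, receptor bin), summarizes pSTAT5 as the
#' geometric mean fluorescence per IL-2 dose and fits the three-parameter
#' Hill dose response.
#'
#' @param binned output of \code{\link{bin_events}}.
#' @param hill_n fixed Hill coefficient.
#' @return data.frame with one row per (condition_id, antigen_dose, bin_id):
#'   base, amplitude, ec50, fit_ok.
#' @export
ccva_hill_fits <- function(binned, hill_n = 1) {
  b <- binned[binned$retained, , drop = FALSE]
  if (!nrow(b)) stop("no retained bins; lower min_events or n_bins_per_axis")
  gm <- stats::aggregate(list(pstat5 = b$pstat5_fi),
                         by = list(condition_id = b$condition_id,
                                   antigen_dose = b$antigen_dose,
                                   bin_id = b$bin_id, il2_dose = b$il2_dose),
                         gmfi)
  keys <- unique(gm[c("condition_id", "antigen_dose", "bin_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- gm[gm$condition_id == keys$condition_id[i] &
              gm$bin_id == keys$bin_id[i], ]
    f <- fit_hill(g$il2_dose, g$pstat5, hill_n = hill_n)
    data.frame(keys[i, , drop = FALSE], base = f$base,
               amplitude = f$amplitude, ec50 = f$ec50, fit_ok = f$fit_ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize per-bin pSTAT5 amplitudes to a reference antigen condition
#'
#' Divides each (bin, condition) fitted amplitude by the amplitude of the
#' same receptor bin in the reference condition (by convention the highest
#' antigen dose), factoring receptor abundance out of the signaling
#' amplitude, then averages across occupied bins per condition.
#'
#' @param fits output of \code{\link{ccva_hill_fits}}.
#' @param reference_condition \code{condition_id} of the reference.
#' @return list (class \code{il2_ccva_map}) with \code{per_bin} (data.frame
#'   condition_id, antigen_dose, bin_id, norm_amplitude) and \code{summary}
#'   (per condition: mean_norm_amplitude, sem, n_bins). Bins without usable
#'   reference coverage are dropped; count in \code{n_dropped}.
#' @export
normalize_amplitudes <- function(fits, reference_condition) {
  ref <- fits[fits$condition_id == reference_condition & fits$fit_ok, ]
  if (!nrow(ref)) stop("reference condition has no usable bins")
  refamp <- stats::setNames(ref$amplitude, ref$bin_id)
  usable <- fits$fit_ok & fits$bin_id %in% names(refamp)[refamp > 0]
  dropped <- sum(!usable)
  d <- fits[usable, , drop = FALSE]
  d$norm_amplitude <- d$amplitude / refamp[d$bin_id]
  summ <- do.call(rbind, lapply(split(d, d$condition_id), function(g) {
    data.frame(condition_id = g$condition_id[1],
               antigen_dose = g$antigen_dose[1],
               mean_norm_amplitude = mean(g$norm_amplitude),
               sem = stats::sd(g$norm_amplitude) / sqrt(nrow(g)),
               n_bins = nrow(g))
  }))
  summ <- summ[order(summ$antigen_dose), ]
  rownames(summ) <- NULL
  structure(list(per_bin = d[c("condition_id", "antigen_dose", "bin_id",
                               "norm_amplitude")],
                 summary = summ, n_dropped = dropped,
                 reference_condition = reference_condition),
            class = "il2_ccva_map")
}

#' Full CCVA pipeline
#'
#' Bin, fit and normalize in one call.
#'
#' @inheritParams bin_events
#' @inheritParams ccva_hill_fits
#' @param reference_condition reference \code{condition_id}; default the
#'   condition with the highest antigen dose.
#' @return an \code{il2_ccva_map}, see \code{\link{normalize_amplitudes}}.
#' @export
ccva <- function(events, n_bins_per_axis = 8, min_events = 20,
                 reference_condition = NULL, hill_n = 1) {
  binned <- bin_events(events, n_bins_per_axis, min_events)
  fits <- ccva_hill_fits(binned, hill_n = hill_n)
  if (is.null(reference_condition)) {
    reference_condition <-
      fits$condition_id[which.max(fits$antigen_dose)]
  }
  normalize_amplitudes(fits, reference_condition)
}

#' @export
print.il2_ccva_map <- function(x, ...) {
  cat("CCVA normalized pSTAT5 amplitudes (reference condition: ",
      x$reference_condition, ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
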