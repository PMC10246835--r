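# Growth phenotypes: growth-curve AUC and model fits, dose-response IC50,
# promoter activity, functional capacity, polysome qPCR quantification.

#' Area under a growth curve
#'
#' Trapezoidal integral of OD over [t0, t1] hours. The curve must cover the
#' full span; edge extrapolation is refused. Endpoints falling between
#' samples are linearly interpolated.
#'
#' @param times hours, strictly increasing.
#' @param od optical densities (600 nm), same length, non-negative.
#' @param t0,t1 integration bounds (default 0-15 h).
#' @return integral in OD*h.
#' @export
#' @importFrom stats approx
growth_auc <- function(times, od, t0 = 0, t1 = 15) {
  stopifnot(length(times) == length(od), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0)) stop("negative OD")
  if (t0 < min(times) || t1 > max(times))
    stop("curve spans [", min(times), ", ", max(times),
         "] h and does not cover [", t0, ", ", t1, "]")
  inner <- times > t0 & times < t1
  tt <- c(t0, times[inner], t1)
  yy <- c(stats::approx(times, od, t0)$y, od[inner],
          stats::approx(times, od, t1)$y)
  sum(diff(tt) * (utils::head(yy, -1L) + utils::tail(yy, -1L)) / 2)
}

#' Modified-Gompertz growth value
#'
#' od0 + A * exp(-exp(mu * e / A * (lag - t) + 1)): asymptote A above the
#' baseline od0, maximum specific growth rate mu (OD/h), lag time (h).
#'
#' @param t time, hours.
#' @param rate mu, maximum slope.
#' @param lag lag time.
#' @param asymptote A.
#' @param od0 baseline OD.
#' @return OD at time t.
#' @export
gompertz_od <- function(t, rate, lag, asymptote, od0 = 0) {
  od0 + asymptote * exp(-exp(rate * exp(1) / asymptote * (lag - t) + 1))
}

#' Fit a bacterial growth model to an OD curve
#'
#' Least-squares fit of the modified Gompertz model (the standard
#' parametrization with interpretable rate / lag / asymptote). Flat or
#' degenerate curves yield a flagged non-converged record rather than an
#' exception.
#'
#' @param times hours (>= 8 points).
#' @param od optical densities.
#' @return list(rate, lag, asymptote, od0, converged, model).
#' @export
fit_growth_model <- function(times, od) {
  stopifnot(length(times) == length(od))
  fail <- list(rate = NA_real_, lag = NA_real_, asymptote = NA_real_,
               od0 = NA_real_, converged = FALSE, model = "gompertz")
  if (length(times) < 8L) stop("need at least 8 points")
  rng <- max(od) - min(od)
  if (rng <= 0 || rng < 0.05 * max(od, 1e-9)) return(fail)
  # slope estimate over ~1 h spans; point-to-point differences are too
  # noise-sensitive at 10-min sampling
  span <- max(1L, which.min(abs(times - times[1] - 1)) - 1L)
  idx <- seq_len(length(od) - span)
  slopes <- (od[idx + span] - od[idx]) / (times[idx + span] - times[idx])
  i_max <- which.max(slopes)
  rate0 <- max(slopes[i_max], 1e-3)
  lag0 <- max(times[i_max] - od[i_max] / rate0, 0)
  # several starts (an exact-optimum start can give a singular gradient);
  # keep the best-RSS convergent fit
  fit <- NULL; best_rss <- Inf
  for (jit in c(1.05, 0.6, 1.8)) {
    start <- list(rate = rate0 * jit, lag = lag0 + 0.1 * jit,
                  asymptote = rng * jit, od0 = min(od) + 1e-3)
    cand <- tryCatch(
      minpack.lm::nlsLM(
        od ~ gompertz_od(times, rate, lag, asymptote, od0),
        start = start,
        lower = c(rate = 1e-6, lag = 0, asymptote = 1e-6, od0 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      rss <- sum(stats::resid(cand)^2)
      if (rss < best_rss) { best_rss <- rss; fit <- cand }
    }
  }
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  list(rate = unname(cf["rate"]), lag = unname(cf["lag"]),
       asymptote = unname(cf["asymptote"]), od0 = unname(cf["od0"]),
       converged = TRUE, model = "gompertz")
}

#' Dose-response IC50 fit
#'
#' Growth integrals per drug concentration are normalized by the 0-drug
#' integral and fit to the logistic g(c) = 1 / (1 + (c / IC50)^h) by least
#' squares, with free Hill slope h. g(IC50) = 0.5 by construction.
#'
#' @param concentrations drug concentrations (must include 0), ug/ml.
#' @param growth growth integrals (e.g. from [growth_auc()]).
#' @return object of class `dose_response`: list(concentrations,
#'   normalized_growth, ic50, hill, converged, reliable).
#' @export
fit_ic50 <- function(concentrations, growth) {
  stopifnot(length(concentrations) == length(growth))
  if (!any(concentrations == 0)) stop("no 0-concentration reference")
  if (length(unique(concentrations)) < 4L) stop("need >= 4 concentrations")
  ref <- mean(growth[concentrations == 0])
  if (ref <= 0) stop("non-positive reference growth")
  if (stats::sd(growth) == 0) stop("all-equal growth across concentrations")
  g <- growth / ref
  pos <- concentrations > 0
  # monotone-increasing growth with dose cannot be summarized by an IC50
  reliable <- stats::cor(concentrations[pos], g[pos],
                         method = "spearman") <= 0
  near <- which.min(abs(g[pos] - 0.5))
  start <- list(lic50 = log(concentrations[pos][near]), h = 1)
  cc <- concentrations[pos]; gg <- g[pos]
  fit <- tryCatch(
    minpack.lm::nlsLM(gg ~ 1 / (1 + (cc / exp(lic50))^h), start = start,
                      lower = c(lic50 = -30, h = 0.05),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(concentrations = concentrations,
                          normalized_growth = g, ic50 = NA_real_,
                          hill = NA_real_, converged = FALSE,
                          reliable = FALSE), class = "dose_response"))
  }
  cf <- stats::coef(fit)
  structure(list(concentrations = concentrations, normalized_growth = g,
                 ic50 = exp(unname(cf["lic50"])), hill = unname(cf["h"]),
                 converged = TRUE, reliable = reliable),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("dose_response: IC50 = ", signif(x$ic50, 4), " ug/ml, hill = ",
      signif(x$hill, 3), if (!x$reliable) " [flagged unreliable]", "\n",
      sep = "")
  invisible(x)
}

#' Promoter activity
#'
#' Ratio between a fluorescent reporter signal and biomass (OD).
#'
#' @param fluorescence reporter signal.
#' @param od optical density (> 0).
#' @return fluorescence / od.
#' @export
promoter_activity <- function(fluorescence, od) {
  if (any(od <= 0)) stop("OD must be positive")
  fluorescence / od
}

#' Enzyme functional capacity
#'
#' Product of relative intracellular soluble abundance and catalytic
#' activity (kcat / KM), in relative units.
#'
#' @param relative_abundance non-negative.
#' @param kcat_over_km non-negative, per uM per second.
#' @return the product.
#' @export
functional_capacity <- function(relative_abundance, kcat_over_km) {
  if (any(relative_abundance < 0) || any(kcat_over_km < 0))
    stop("inputs must be non-negative")
  relative_abundance * kcat_over_km
}

#' qPCR record for one mRNA fraction
#'
#' @param ct_target threshold cycle of the gene of interest.
#' @param ct_ref threshold cycle of the reference gene.
#' @param fraction "total" or "polysomal".
#' @return object of class `qpcr_record` with the delta-Ct precomputed.
#' @export
qpcr_record <- function(ct_target, ct_ref, fraction = c("total", "polysomal")) {
  fraction <- match.arg(fraction)
  if (!is.finite(ct_target) || !is.finite(ct_ref) ||
      ct_target <= 0 || ct_ref <= 0)
    stop("Ct values must be finite and positive")
  structure(list(ct_target = ct_target, ct_ref = ct_ref,
                 dct = ct_target - ct_ref, fraction = fraction),
            class = "qpcr_record")
}

#' Polysome-engagement log ratio
#'
#' Per fraction the relative abundance is 2^(-dCt) with dCt =
#' Ct(target) - Ct(reference); the returned value is
#' log2(abundance_polysomal / abundance_total) = dCt_total - dCt_polysomal.
#' Greater engagement of the transcript with polysomes increases the value.
#'
#' @param polysomal `qpcr_record` for the polysomal fraction.
#' @param total `qpcr_record` for the total fraction.
#' @return log2 abundance ratio.
#' @export
polysome_log_ratio <- function(polysomal, total) {
  stopifnot(inherits(polysomal, "qpcr_record"), inherits(total, "qpcr_record"))
  if (polysomal$fraction != "polysomal" || total$fraction != "total")
    stop("pass the polysomal and total fractions in that order")
  total$dct - polysomal$dct
}
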