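#' Hill (four-parameter logistic) dose-response parameters
#'
#' Viability parameterization of the 4PL curve,
#' \deqn{v(d) = floor + (ceiling - floor) / (1 + (d/ic50)^{slope}),}
#' monotone decreasing in dose for `slope > 0`. Effects are reported as
#' percent inhibition, `100 * (1 - v)`.
#'
#' @param floor lower viability asymptote (fraction, default 0).
#' @param ceiling upper viability asymptote (fraction, default 1).
#' @param ic50 dose at half-maximal inhibition (same units as doses).
#' @param slope Hill slope, strictly positive.
#' @return an object of class `hill_params`.
#' @export
hill_params <- function(ic50, slope, floor = 0, ceiling = 1) {
  if (!is.finite(ic50) || ic50 <= 0) .fail("ic50 must be positive, got %s", ic50)
  if (!is.finite(slope) || slope <= 0) .fail("slope must be positive, got %s", slope)
  if (ceiling <= floor) .fail("ceiling (%s) must exceed floor (%s)", ceiling, floor)
  structure(list(floor = floor, ceiling = ceiling, ic50 = ic50, slope = slope),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill curve: IC50 = %g, slope = %g, asymptotes [%g, %g]\n",
              x$ic50, x$slope, x$floor, x$ceiling))
  invisible(x)
}

#' Viability predicted by a Hill curve
#'
#' @param curve a [hill_params()] object.
#' @param dose non-negative dose vector.
#' @return viability fractions.
#' @export
hill_viability <- function(curve, dose) {
  stopifnot(inherits(curve, "hill_params"), all(dose >= 0))
  curve$floor + (curve$ceiling - curve$floor) / (1 + (dose / curve$ic50)^curve$slope)
}

#' Percent inhibition predicted by a Hill curve
#'
#' @inheritParams hill_viability
#' @return percent inhibition, `100 * (1 - viability)`.
#' @export
hill_effect <- function(curve, dose) 100 * (1 - hill_viability(curve, dose))

#' Invert a Hill curve: dose producing a given percent inhibition
#'
#' Analytic inversion of the viability 4PL. Effects at or below the curve's
#' minimum attainable inhibition map to 0; effects at or above the maximum
#' attainable inhibition map to `Inf` (the curve saturates).
#'
#' @param curve a [hill_params()] object.
#' @param effect percent inhibition (0-100 scale).
#' @return dose (possibly 0 or `Inf`).
#' @export
hill_inverse <- function(curve, effect) {
  stopifnot(inherits(curve, "hill_params"))
  v <- 1 - effect / 100                     # target viability
  lo <- 100 * (1 - curve$ceiling)           # min attainable inhibition
  hi <- 100 * (1 - curve$floor)             # max attainable inhibition
  out <- numeric(length(effect))
  out[effect <= lo] <- 0
  out[effect >= hi] <- Inf
  mid <- effect > lo & effect < hi
  if (any(mid)) {
    frac <- (curve$ceiling - v[mid]) / (v[mid] - curve$floor)
    out[mid] <- curve$ic50 * frac^(1 / curve$slope)
  }
  out
}

#' CCK-8 cell viability from raw absorbances
#'
#' `(dosing - blank) / (control - blank)`, the standard CCK-8 normalization.
#' Values slightly above 1 are retained (they reflect assay noise); set
#' `clip = TRUE` to truncate into `[0, 1]`.
#'
#' @param dosing absorbance of treated wells.
#' @param blank absorbance of cell-free blank wells.
#' @param control absorbance of untreated control wells.
#' @param clip truncate the result into `[0, 1]`? Default `FALSE`.
#' @return viability fractions.
#' @export
viability <- function(dosing, blank, control, clip = FALSE) {
  if (any(control <= blank))
    .fail("control absorbance must exceed blank absorbance")
  v <- (dosing - blank) / (control - blank)
  if (clip) v <- pmin(pmax(v, 0), 1)
  v
}

#' Fit a Hill curve to dose-viability data
#'
#' Least-squares 4PL fit parameterized internally on log(IC50) for
#' conditioning, with a deterministic multi-start over a log-spaced IC50 grid
#' spanning the dosed range. Replicates at the same dose are averaged before
#' fitting, with inverse-variance weights when replicate SDs are available
#' (>= 2 replicates per dose and nonzero scatter). By default the asymptotes
#' are fixed at floor = 0, ceiling = 1, which keeps the fit identifiable when
#' the dose range covers the asymptote neighborhoods poorly; `fix_floor_ceiling
#' = FALSE` frees all four parameters (requires >= 4 distinct doses).
#'
#' @param dose dose vector (positive).
#' @param viab viability fractions, same length.
#' @param fix_floor_ceiling fix asymptotes at 0/1? Default `TRUE`.
#' @param n_starts size of the IC50 multi-start grid.
#' @return a list of class `dose_response_fit` with elements `params`
#'   ([hill_params()]), `residual_sse`, `converged`, `n_points`, and
#'   `extrapolated` (IC50 outside the dosed range).
#' @export
fit_hill <- function(dose, viab, fix_floor_ceiling = TRUE, n_starts = 12L) {
  stopifnot(length(dose) == length(viab), all(dose > 0), all(is.finite(viab)))
  ud <- sort(unique(dose))
  need <- if (fix_floor_ceiling) 2L else 4L
  if (length(ud) < need)
    .fail("need >= %d distinct doses for this fit, got %d", need, length(ud))

  # average replicates; inverse-variance weights where replicate scatter exists
  mv <- tapply(viab, dose, mean)
  sv <- tapply(viab, dose, stats::sd)
  nrep <- tapply(viab, dose, length)
  d <- as.numeric(names(mv)); o <- order(d)
  d <- d[o]; mv <- as.numeric(mv)[o]; sv <- as.numeric(sv)[o]; nrep <- as.numeric(nrep)[o]
  w <- rep(1, length(d))
  if (all(nrep >= 2) && all(is.finite(sv)) && all(sv > 0)) w <- nrep / sv^2

  bad_fit <- function() {
    structure(list(params = NULL, residual_sse = NA_real_, converged = FALSE,
                   n_points = length(d), extrapolated = NA),
              class = "dose_response_fit")
  }
  if (stats::sd(mv) < 1e-8) return(bad_fit())  # flat data: no IC50 in range

  grid <- exp(seq(log(min(d)), log(max(d)), length.out = n_starts))
  best <- NULL
  for (ic0 in grid) {
    fit <- tryCatch({
      if (fix_floor_ceiling) {
        minpack.lm::nlsLM(
          mv ~ 1 / (1 + exp(s * (log(d) - lic))),
          start = list(lic = log(ic0), s = 1),
          lower = c(log(min(d)) - 10, 1e-3), upper = c(log(max(d)) + 10, 50),
          weights = w, control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          mv ~ fl + (ce - fl) / (1 + exp(s * (log(d) - lic))),
          start = list(fl = max(0, min(mv)), ce = min(1.2, max(mv)),
                       lic = log(ic0), s = 1),
          lower = c(-0.2, 0.2, log(min(d)) - 10, 1e-3),
          upper = c(0.5, 1.5, log(max(d)) + 10, 50),
          weights = w, control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(bad_fit())

  cf <- stats::coef(best$fit)
  pars <- if (fix_floor_ceiling) {
    hill_params(ic50 = exp(cf[["lic"]]), slope = cf[["s"]])
  } else {
    if (cf[["ce"]] <= cf[["fl"]]) return(bad_fit())
    hill_params(ic50 = exp(cf[["lic"]]), slope = cf[["s"]],
                floor = cf[["fl"]], ceiling = cf[["ce"]])
  }
  structure(list(params = pars, residual_sse = best$sse, converged = TRUE,
                 n_points = length(d),
                 extrapolated = pars$ic50 < min(d) || pars$ic50 > max(d)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) cat("Hill fit: did not converge\n")
  else cat(sprintf("Hill fit: IC50 = %.4g (%s), slope = %.3g, SSE = %.3g on %d doses\n",
                   x$params$ic50, if (x$extrapolated) "extrapolated" else "in range",
                   x$params$slope, x$residual_sse, x$n_points))
  invisible(x)
}

#' Three-tier toxicity classification from IC50
#'
#' Tiers follow the study's grouping of hepatocyte IC50 values:
#' above 450 ug/mL is low toxicity, below 390 ug/mL is high toxicity, and
#' the closed interval 390-450 ug/mL is medium toxicity.
#'
#' @param ic50 IC50 values in ug/mL (positive).
#' @return character vector in `c("low", "medium", "high")`.
#' @export
classify_toxicity_tier <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    .fail("ic50 must be positive and finite")
  ifelse(ic50 > 450, "low", ifelse(ic50 < 390, "high", "medium"))
}
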