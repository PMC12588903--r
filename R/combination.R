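#' Loewe equivalent-dose conversion between two dose-response curves
#'
#' Converts a dose of one drug into the dose of a target drug producing the
#' same effect (iso-effective dose): the other drug's effect at `dose_other`
#' is computed and pushed through the target curve's inverse. A zero dose maps
#' to zero. When the other drug's effect exceeds the target curve's attainable
#' ceiling the equivalent dose is `Inf` (flagged downstream as saturation).
#'
#' @param curve_target [hill_params()] of the drug whose dose units we convert
#'   into.
#' @param curve_other [hill_params()] of the drug whose dose is given.
#' @param dose_other non-negative dose of the other drug.
#' @return equivalent dose in target-drug units (possibly `Inf`).
#' @export
equivalent_dose <- function(curve_target, curve_other, dose_other) {
  stopifnot(inherits(curve_target, "hill_params"),
            inherits(curve_other, "hill_params"))
  if (any(dose_other < 0)) .fail("dose_other must be non-negative")
  eff <- hill_effect(curve_other, dose_other)
  out <- hill_inverse(curve_target, eff)
  out[dose_other == 0] <- 0
  out
}

#' Construct a combination ray
#'
#' A ray pairs escalating doses of two drugs with the observed combined
#' effect (percent inhibition) and the two drugs' single-agent Hill curves.
#'
#' @param dose1,dose2 positive dose vectors (same length).
#' @param y_obs observed percent inhibition per pair, in `[0, 100]`.
#' @param curve1,curve2 [hill_params()] for each drug alone.
#' @param drug_names names of the two drugs (reporting only).
#' @return an object of class `combination_ray`.
#' @export
combination_ray <- function(dose1, dose2, y_obs, curve1, curve2,
                            drug_names = c("drug1", "drug2")) {
  stopifnot(length(dose1) == length(dose2), length(dose1) == length(y_obs))
  if (any(dose1 <= 0) || any(dose2 <= 0)) .fail("doses must be positive")
  if (any(y_obs < 0 | y_obs > 100)) .fail("observed effects must lie in [0, 100]")
  stopifnot(inherits(curve1, "hill_params"), inherits(curve2, "hill_params"))
  structure(list(dose1 = dose1, dose2 = dose2, y_obs = y_obs,
                 curve1 = curve1, curve2 = curve2, drug_names = drug_names),
            class = "combination_ray")
}

#' Predicted additive effects from both drugs' perspectives
#'
#' The "One-belt" construction: for each dose pair the second drug's dose is
#' converted to target-drug units and added, giving two predicted additive
#' effects — `f` with drug 1 as the target, `g` with drug 2 as the target.
#' The pointwise interval between them is the additive belt. When an
#' equivalent dose is infinite the prediction saturates at the target curve's
#' maximum attainable inhibition and is flagged.
#'
#' @param ray a [combination_ray()].
#' @return data.frame with columns `f`, `g`, `belt_lo`, `belt_hi`,
#'   `saturated_f`, `saturated_g`.
#' @export
predict_additive <- function(ray) {
  stopifnot(inherits(ray, "combination_ray"))
  eq1 <- equivalent_dose(ray$curve1, ray$curve2, ray$dose2)  # drug2 in drug1 units
  eq2 <- equivalent_dose(ray$curve2, ray$curve1, ray$dose1)  # drug1 in drug2 units
  sat_f <- !is.finite(eq1)
  sat_g <- !is.finite(eq2)
  f <- ifelse(sat_f, 100 * (1 - ray$curve1$floor),
              hill_effect(ray$curve1, ray$dose1 + eq1))
  g <- ifelse(sat_g, 100 * (1 - ray$curve2$floor),
              hill_effect(ray$curve2, ray$dose2 + eq2))
  data.frame(f = f, g = g,
             belt_lo = pmin(f, g), belt_hi = pmax(f, g),
             saturated_f = sat_f, saturated_g = sat_g)
}

#' Dose-based combination indices
#'
#' `CI_d1 = y_obs / f` and `CI_d2 = y_obs / g`, the observed effect relative
#' to each predicted additive effect. A zero observed effect yields CI = 0.
#' Values are exact; rounding happens only at the reporting layer
#' ([analyze_ray()]).
#'
#' @param y_obs observed percent inhibition.
#' @param f,g predicted additive effects (percent) from the two perspectives.
#' @return data.frame with columns `ci_d1`, `ci_d2`.
#' @export
combination_index <- function(y_obs, f, g) {
  if (any(c(y_obs, f, g) < 0)) .fail("effects must be non-negative")
  if (any(f == 0 & y_obs > 0) || any(g == 0 & y_obs > 0))
    .fail("predicted additive effect is 0 with nonzero observed effect; CI undefined")
  data.frame(ci_d1 = ifelse(y_obs == 0, 0, y_obs / f),
             ci_d2 = ifelse(y_obs == 0, 0, y_obs / g))
}

#' Interaction judgment from a CI pair
#'
#' Default rule (reconstructed from the reported judgment pattern): both
#' indices above 1 is synergistic, both at or below 1 is antagonistic, and a
#' split pair — the observed line inside the additive belt — is additive.
#' `mode = "strict"` applies the literal published footnote rule
#' (synergy both > 1; addition both <= 1; antagonism both < 1), which
#' overlaps for both-below-1 pairs and leaves split pairs unclassified
#' (`NA`); it is retained for fidelity only.
#'
#' @param ci_d1,ci_d2 combination indices (non-negative).
#' @param mode `"pattern"` (default) or `"strict"`.
#' @return character vector in
#'   `c("antagonistic", "additive", "synergistic")` (or `NA` in strict mode).
#' @export
judge_interaction <- function(ci_d1, ci_d2, mode = c("pattern", "strict")) {
  mode <- match.arg(mode)
  if (any(c(ci_d1, ci_d2) < 0)) .fail("CI values must be non-negative")
  if (mode == "pattern") {
    ifelse(ci_d1 > 1 & ci_d2 > 1, "synergistic",
           ifelse(ci_d1 <= 1 & ci_d2 <= 1, "antagonistic", "additive"))
  } else {
    ifelse(ci_d1 > 1 & ci_d2 > 1, "synergistic",
           ifelse(ci_d1 < 1 & ci_d2 < 1, "antagonistic",
                  ifelse(ci_d1 <= 1 & ci_d2 <= 1, "additive", NA_character_)))
  }
}

#' Full "One-belt, One-line" analysis of a combination ray
#'
#' One row per dose pair: doses, both predicted additive effects, the observed
#' effect, both combination indices, and the interaction judgment. Effects are
#' reported at 2 decimals and CI values at 4 decimals (half-up), matching the
#' field's reporting convention; the `belt` attribute carries the unrounded
#' additive band for plotting.
#'
#' @param ray a [combination_ray()].
#' @param mode judgment rule passed to [judge_interaction()].
#' @return data.frame with attribute `belt` (list of `lo`/`hi` polylines).
#' @export
analyze_ray <- function(ray, mode = "pattern") {
  stopifnot(inherits(ray, "combination_ray"))
  add <- predict_additive(ray)
  ci <- combination_index(ray$y_obs, add$f, add$g)
  out <- data.frame(
    dose1 = ray$dose1, dose2 = ray$dose2,
    f = round_half_up(add$f, 2), g = round_half_up(add$g, 2),
    y_obs = round_half_up(ray$y_obs, 2),
    ci_d1 = round_half_up(ci$ci_d1, 4), ci_d2 = round_half_up(ci$ci_d2, 4),
    judgment = judge_interaction(ci$ci_d1, ci$ci_d2, mode = mode),
    stringsAsFactors = FALSE
  )
  names(out)[1:2] <- paste0("dose_", ray$drug_names)
  attr(out, "belt") <- list(dose1 = ray$dose1, lo = add$belt_lo, hi = add$belt_hi)
  out
}

#' Read a combination table (doses, predicted additive and observed effects)
#'
#' Reads a CSV with columns `dose1, dose2, f, g, y_obs` (extra columns such as
#' previously reported CI values or judgments are carried through). Used both
#' for external ray tables and for the packaged reference fixture.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_combination_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose1", "dose2", "f", "g", "y_obs")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .fail("combination table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(tab$dose1 <= 0) || any(tab$dose2 <= 0)) .fail("doses must be positive")
  tab
}

#' Recompute CI columns and judgments for a combination table
#'
#' Applies [combination_index()] and [judge_interaction()] to a table of
#' predicted additive and observed effects (e.g., one read by
#' [read_combination_table()]); no curve fitting is involved, so this works
#' directly on published effect columns.
#'
#' @param tab data.frame with columns `f`, `g`, `y_obs`.
#' @param mode judgment rule passed to [judge_interaction()].
#' @param digits CI rounding at the reporting layer (default 4, half-up).
#' @return `tab` with columns `ci_d1`, `ci_d2`, `judgment` (re)computed.
#' @export
combination_table_ci <- function(tab, mode = "pattern", digits = 4) {
  ci <- combination_index(tab$y_obs, tab$f, tab$g)
  tab$ci_d1 <- round_half_up(ci$ci_d1, digits)
  tab$ci_d2 <- round_half_up(ci$ci_d2, digits)
  tab$judgment <- judge_interaction(ci$ci_d1, ci$ci_d2, mode = mode)
  tab
}

#' Exact Loewe-additive effect for two Hill curves
#'
#' Solves the Loewe additivity equation
#' \eqn{d_1 / D_1(y) + d_2 / D_2(y) = 1} for the combined effect `y`, where
#' `D_i(y)` is the dose of drug `i` alone producing effect `y`. For curves
#' with equal Hill slopes this coincides with the equivalent-dose additive
#' prediction; with unequal slopes it lies inside the additive belt. Solved
#' by bisection on effect to 1e-9 in dose-sum units.
#'
#' @param curve1,curve2 [hill_params()] objects.
#' @param dose1,dose2 non-negative doses (vectors, same length).
#' @return percent inhibition of the exactly additive combination.
#' @export
loewe_effect <- function(curve1, curve2, dose1, dose2) {
  stopifnot(length(dose1) == length(dose2))
  lo_eff <- pmax(100 * (1 - curve1$ceiling), 100 * (1 - curve2$ceiling))
  hi_eff <- min(100 * (1 - curve1$floor), 100 * (1 - curve2$floor))
  vapply(seq_along(dose1), function(i) {
    d1 <- dose1[i]; d2 <- dose2[i]
    if (d1 == 0 && d2 == 0) return(max(hill_effect(curve1, 0), hill_effect(curve2, 0)))
    if (d1 == 0) return(hill_effect(curve2, d2))
    if (d2 == 0) return(hill_effect(curve1, d1))
    gfun <- function(y) {
      D1 <- hill_inverse(curve1, y); D2 <- hill_inverse(curve2, y)
      d1 / D1 + d2 / D2 - 1       # decreasing in y
    }
    lo <- max(lo_eff[1], 1e-9); hi <- hi_eff - 1e-9
    if (gfun(hi) > 0) return(hi_eff)   # effect saturates
    stats::uniroot(gfun, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}
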