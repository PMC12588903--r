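# Univariate marker statistics: Welch t-tests (with a one-sample mode),
# Benjamini-Hochberg FDR, the VIP-and-q marker rule, and one-way ANOVA with
# Tukey HSD pairwise comparisons.

#' Welch two-sample t-test (or one-sample mode)
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom; with `mu`
#' given and `group_b = NULL`, a one-sample test of `group_a` against `mu`.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param mu reference mean for the one-sample mode.
#' @return list with `t`, `p`, `df`, `estimate` (mean difference).
#' @export
welch_t_test <- function(group_a, group_b = NULL, mu = 0) {
  if (length(group_a) < 2) .fail("group_a needs at least 2 values")
  if (is.null(group_b)) {
    if (stats::sd(group_a) == 0) {
      eq <- isTRUE(all.equal(mean(group_a), mu))
      return(list(t = if (eq) 0 else sign(mean(group_a) - mu) * Inf,
                  p = if (eq) 1 else 0, df = length(group_a) - 1,
                  estimate = mean(group_a) - mu))
    }
    ht <- stats::t.test(group_a, mu = mu)
  } else {
    if (length(group_b) < 2) .fail("group_b needs at least 2 values")
    if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
      d <- mean(group_a) - mean(group_b)
      return(list(t = if (d == 0) 0 else sign(d) * Inf, p = if (d == 0) 1 else 0,
                  df = length(group_a) + length(group_b) - 2, estimate = d))
    }
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  }
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       estimate = if (is.null(group_b)) unname(ht$estimate) - mu
                  else unname(diff(rev(ht$estimate))))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} (m p_(j) / j)` on sorted p-values, clipped at 1 and
#' mapped back to the input order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    .fail("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Flag differential markers by the VIP-and-q rule
#'
#' A compound is a marker when its VIP strictly exceeds `vip_threshold`
#' (default 1) and its BH q-value is strictly below `q_threshold`
#' (default 0.05). Report sorted by VIP descending.
#'
#' @param vip VIP values (named by compound, optional).
#' @param q q-values, same length.
#' @param p raw p-values (carried through if given).
#' @param t t-statistics (carried through if given).
#' @param vip_threshold,q_threshold decision thresholds.
#' @return data.frame `compound_id, vip, t_statistic, p_value, q_value,
#'   is_marker`, sorted by VIP descending.
#' @export
select_markers <- function(vip, q, p = NULL, t = NULL,
                           vip_threshold = 1.0, q_threshold = 0.05) {
  if (length(vip) != length(q)) .fail("vip and q must have equal length")
  ids <- if (!is.null(names(vip))) names(vip) else sprintf("V%02d", seq_along(vip))
  out <- data.frame(compound_id = ids, vip = unname(vip),
                    t_statistic = if (is.null(t)) NA_real_ else unname(t),
                    p_value = if (is.null(p)) NA_real_ else unname(p),
                    q_value = unname(q),
                    is_marker = unname(vip > vip_threshold & q < q_threshold),
                    stringsAsFactors = FALSE)
  out[order(-out$vip), , drop = FALSE]
}

#' Per-compound two-group marker statistics
#'
#' Convenience wrapper running [welch_t_test()] on every column of a
#' concentration matrix split by a two-level grouping, with BH correction,
#' and joining the result to an OPLS-DA VIP vector via [select_markers()].
#'
#' @param X batches x compounds matrix.
#' @param y two-class vector over rows.
#' @param vip VIP per column (e.g., from [fit_oplsda()]).
#' @param ... thresholds passed to [select_markers()].
#' @return the [select_markers()] report.
#' @export
marker_table <- function(X, y, vip, ...) {
  cls <- sort(unique(as.character(y)))
  if (length(cls) != 2) .fail("y must have exactly 2 classes")
  stat <- apply(X, 2, function(col)
    unlist(welch_t_test(col[y == cls[1]], col[y == cls[2]])[c("t", "p")]))
  q <- benjamini_hochberg(stat["p", ])
  select_markers(vip, q, p = stat["p", ], t = stat["t", ], ...)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values numeric response vector.
#' @param group_labels grouping vector (>= 2 groups, each >= 2 values).
#' @return list with `f`, `p` (omnibus), and `pairwise` (data.frame of group
#'   pairs with mean difference and Tukey-adjusted p).
#' @export
one_way_anova_tukey <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2) .fail("need at least 2 groups")
  if (any(table(g) < 2)) .fail("every group needs at least 2 values")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                             diff = unname(tk[, "diff"]),
                             p_adj = unname(tk[, "p adj"]),
                             stringsAsFactors = FALSE))
}
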