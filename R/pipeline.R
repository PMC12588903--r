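# End-to-end orchestration: qualification -> grouping -> dose-response tiers
# -> OPLS-DA markers -> combination analysis -> chromaticity, written to a
# run directory with a seeded, hash-carrying manifest.

#' Pipeline configuration
#'
#' Bundles every tunable of the evaluation pipeline with its study default:
#' unit-variance autoscaling, Ward/Euclidean HCA at k = 4 composition groups,
#' one orthogonal OPLS-DA component, a 200x permutation test, marker
#' thresholds VIP > 1 and q < 0.05, toxicity tier cutoffs 390/450 ug/mL, and
#' CI reporting at 4 decimals.
#'
#' @param synthetic a [synthetic_config()] used when no input files are given.
#' @param scaling_mode autoscaling mode for chemometrics.
#' @param hca_linkage,hca_metric,hca_k clustering controls.
#' @param n_orthogonal OPLS-DA orthogonal components.
#' @param n_permutations permutation-test size (default 200).
#' @param vip_threshold,q_threshold marker rule thresholds.
#' @param tier_cutoffs `c(high_below, low_above)` IC50 cutoffs in ug/mL.
#' @param ci_digits CI reporting decimals.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(seed = seed),
                            scaling_mode = "unit_variance",
                            hca_linkage = "ward", hca_metric = "euclidean",
                            hca_k = 4,
                            n_orthogonal = 1, n_permutations = 200,
                            vip_threshold = 1.0, q_threshold = 0.05,
                            tier_cutoffs = c(390, 450), ci_digits = 4,
                            seed = 1L) {
  if (tier_cutoffs[1] >= tier_cutoffs[2]) .fail("tier cutoffs must be ordered")
  if (n_permutations < 1 || hca_k < 1) .fail("counts must be positive")
  structure(list(synthetic = synthetic, scaling_mode = scaling_mode,
                 hca_linkage = hca_linkage, hca_metric = hca_metric,
                 hca_k = hca_k, n_orthogonal = n_orthogonal,
                 n_permutations = n_permutations,
                 vip_threshold = vip_threshold, q_threshold = q_threshold,
                 tier_cutoffs = tier_cutoffs, ci_digits = ci_digits,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full evaluation pipeline on a synthetic study
#'
#' Stages, mirroring the evaluation model's order: (1) generate (or accept) a
#' compound table and qualify batches by THSG content; (2) cluster the
#' autoscaled profiles (HCA) and validate with PCA; (3) fit per-group
#' viability curves and classify toxicity tiers; (4) OPLS-DA of the least- vs
#' most-toxic groups with permutation validation and VIP/t/q marker
#' selection; (5) "One-belt, One-line" combination analysis of the two top
#' markers' synthetic ray; (6) chromaticity summaries, clustering, and
#' IC50 regression. Each stage writes its table under `out_dir`, and a JSON
#' manifest records the config, seed, and md5 of every output.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created; contents overwritten).
#' @param skip_chromaticity skip stage 6 (recorded in the manifest).
#' @return invisibly, a list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir,
                         skip_chromaticity = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  syn <- cfg$synthetic

  # 1. compound table + qualification
  tab <- generate_compound_table(syn)
  truth <- attr(tab, "group")
  qual <- qualify_batches(tab)
  utils::write.csv(qual, file.path(out_dir, "qualification.csv"), row.names = FALSE)
  res$qualification <- qual

  # 2. chemometric grouping
  sc <- autoscale(tab$concentrations, mode = cfg$scaling_mode)
  cl <- hca(sc, linkage = cfg$hca_linkage, metric = cfg$hca_metric, k = cfg$hca_k)
  pca <- fit_pca(sc, n_components = min(5, ncol(sc$values)))
  q2 <- pca_q2(sc, n_components = 2, seed = cfg$seed)
  groups <- data.frame(batch_id = rownames(tab$concentrations),
                       cluster = unname(cl$labels),
                       true_group = unname(truth), stringsAsFactors = FALSE)
  utils::write.csv(groups, file.path(out_dir, "group_labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(explained_variance_fraction = pca$explained_variance_fraction,
                            r2x_cum = pca$r2x_cum, q2 = q2),
                       file.path(out_dir, "pca_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  res$groups <- groups; res$pca <- pca; res$pca_q2 <- q2

  # 3. dose-response tiers per group
  doses <- c(1, 10, 50, 100, 200, 300, 400, 500, 700, 1000)
  tiers <- do.call(rbind, lapply(seq_len(syn$n_groups), function(gi) {
    g <- LETTERS[gi]
    plate <- generate_viability_plate(syn$hill_params_by_group[[g]], doses,
                                      syn$noise_sd_viability,
                                      seed = derive_seed(syn$seed, 10L + gi))
    v <- viability(plate$absorbance_dosing, plate$absorbance_blank,
                   plate$absorbance_control)
    fit <- fit_hill(plate$dose, v)
    data.frame(group = g,
               ic50 = if (fit$converged) fit$params$ic50 else NA_real_,
               converged = fit$converged,
               tier = if (fit$converged) classify_toxicity_tier(fit$params$ic50)
                      else NA_character_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tiers, file.path(out_dir, "toxicity_tiers.csv"), row.names = FALSE)
  res$tiers <- tiers

  # 4. markers: least toxic (B) vs most toxic (C) synthetic groups
  sel <- truth %in% c("B", "C")
  Xbc <- autoscale(tab$concentrations[sel, ], mode = cfg$scaling_mode)
  y <- truth[sel]
  opls <- fit_oplsda(Xbc, y, n_orthogonal = cfg$n_orthogonal, seed = cfg$seed)
  perm <- permutation_test(Xbc, y, n_orthogonal = cfg$n_orthogonal,
                           n_permutations = cfg$n_permutations, seed = cfg$seed)
  markers <- marker_table(tab$concentrations[sel, ], y, opls$vip,
                          vip_threshold = cfg$vip_threshold,
                          q_threshold = cfg$q_threshold)
  utils::write.csv(markers, file.path(out_dir, "marker_report.csv"), row.names = FALSE)
  jsonlite::write_json(list(r2x = opls$r2x, r2y = opls$r2y, q2 = opls$q2,
                            n_orthogonal = opls$n_orthogonal,
                            permutation_valid = perm$valid,
                            q2_intercept = perm$q2_intercept),
                       file.path(out_dir, "oplsda_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  res$oplsda <- opls; res$permutation <- perm; res$markers <- markers

  # 5. combination analysis of a synthetic two-marker ray (equal-slope
  # curves at the study's single-agent IC50 scale)
  curveT <- hill_params(417.0, 3); curveE <- hill_params(12.7, 3)
  pairs <- cbind(seq(50, 550, length.out = 10), seq(1.5, 22.5, length.out = 10))
  ray <- generate_combination_ray(curveT, curveE, pairs,
                                  interaction = "potency_shift",
                                  shift_factor = 1.6, noise_sd = 0,
                                  seed = cfg$seed)
  comb <- analyze_ray(ray)
  utils::write.csv(comb, file.path(out_dir, "combination_table.csv"), row.names = FALSE)
  res$combination <- comb

  # 6. chromaticity
  if (skip_chromaticity) {
    res$chromaticity <- NULL
  } else {
    recs <- generate_chromaticity(syn)
    summ <- batch_color_summaries(recs)
    ic50_by_group <- vapply(syn$hill_params_by_group, `[[`, numeric(1), "ic50")
    ic50 <- stats::setNames(ic50_by_group[match(truth, names(ic50_by_group))],
                            names(truth))
    reg <- color_toxicity_regression(summ, ic50)
    chca <- color_hca(summ, k = min(cfg$hca_k, 3))
    utils::write.csv(summ, file.path(out_dir, "color_summaries.csv"), row.names = FALSE)
    utils::write.csv(reg, file.path(out_dir, "color_regression.csv"), row.names = FALSE)
    res$chromaticity <- list(summaries = summ, regression = reg, hca = chca)
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config = list(scaling_mode = cfg$scaling_mode, hca_linkage = cfg$hca_linkage,
                  hca_metric = cfg$hca_metric, hca_k = cfg$hca_k,
                  n_orthogonal = cfg$n_orthogonal,
                  n_permutations = cfg$n_permutations,
                  vip_threshold = cfg$vip_threshold, q_threshold = cfg$q_threshold,
                  tier_cutoffs = cfg$tier_cutoffs, ci_digits = cfg$ci_digits,
                  seed = cfg$seed),
    skipped = if (skip_chromaticity) "chromaticity" else character(0),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
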