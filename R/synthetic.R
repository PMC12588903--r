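# Synthetic study-design generator. Emulates the 61-batch x 26-compound
# commercial PM design: four latent composition groups, stilbene glycosides
# dominant (THSG ~96% of its class), Hill-shaped HepaRG viability with
# group-linked IC50 tiers, and group-linked chromaticity of decoction pieces.

.COMPOUND_CLASSES <- c(rep("anthraquinone", 12), rep("stilbene_glycoside", 5),
                       rep("flavonoid", 4), rep("phenol", 5))
.COMPOUND_IDS <- {
  ids <- sprintf("C%02d", 1:26)
  ids[1] <- "emodin"; ids[5] <- "EG"; ids[13] <- "THSG"; ids[18] <- "catechin"
  ids
}

# Per-group compound means (mg/g). The four reported marker compounds carry
# strong group structure — THSG (col 13) and EG (col 5) separate the
# low-toxicity group B from the high-toxicity group C; emodin (col 1) and
# catechin (col 18) additionally separate B from the medium group D — while
# the remaining 22 compounds get only mild class-level group multipliers, so
# grouping is recoverable from the whole profile but the discriminant weight
# concentrates where the study found it. Composition stays in the reported
# ranges: anthraquinone totals ~0.2-8 mg/g, stilbene-glycoside totals
# dominated by THSG (>90% of the class), group A THSG below the 10 mg/g
# qualification limit.
.default_compound_means <- function(n_groups = 4) {
  base <- numeric(26)
  base[1:12] <- c(0.45, 0.16, 0.03, 0.05, 0.35, 0.03, 0.22, 0.03, 0.20, 0.03,
                  0.02, 0.28)                       # anthraquinones
  base[13:17] <- c(12.5, 0.22, 0.06, 0.03, 0.16)    # stilbene glycosides
  base[18:21] <- c(0.35, 0.25, 0.10, 0.06)          # flavonoids
  base[22:26] <- c(0.08, 0.05, 0.03, 0.025, 0.015)  # phenols
  class_mult <- rbind(                              # class-level group effects
    A = c(aq = 0.40, sg = 0.55, fl = 1.70, ph = 0.60),
    B = c(aq = 1.00, sg = 1.00, fl = 1.00, ph = 1.00),
    C = c(aq = 1.40, sg = 1.14, fl = 0.60, ph = 1.35),
    D = c(aq = 1.20, sg = 1.07, fl = 1.60, ph = 1.10))
  cls_idx <- rep(1:4, c(12, 5, 4, 5))
  markers <- rbind(                                 # strong marker structure
    A = c(emodin = 0.45, EG = 0.40, THSG = 6.0, catechin = 0.30),
    B = c(emodin = 0.40, EG = 0.35, THSG = 12.5, catechin = 0.35),
    C = c(emodin = 0.50, EG = 2.80, THSG = 43.0, catechin = 0.40),
    D = c(emodin = 1.10, EG = 1.30, THSG = 25.0, catechin = 0.75))
  m <- t(vapply(seq_len(n_groups), function(g) {
    v <- base * class_mult[g, cls_idx]
    v[c(1, 5, 13, 18)] <- markers[g, ]
    v
  }, numeric(26)))
  dimnames(m) <- list(LETTERS[seq_len(n_groups)], .COMPOUND_IDS)
  m
}

.default_chroma_means <- function(n_groups = 4) {
  # mean sRGB per group (B white, C light yellow, D yellow-brown, A pale);
  # region offsets darken the cork and lighten the xylem.
  base <- rbind(A = c(190, 180, 160),
                B = c(205, 198, 188),
                C = c(215, 190, 115),
                D = c(150, 118, 80))[seq_len(n_groups), , drop = FALSE]
  regions <- c("cork", "phloem", "central_xylem", "heteromorphic_bundles")
  offs <- c(cork = -45, phloem = 0, central_xylem = 20, heteromorphic_bundles = -10)
  out <- list()
  for (g in rownames(base)) {
    rg <- sapply(regions, function(r) pmin(pmax(base[g, ] + offs[[r]], 5), 250))
    lab <- t(apply(rg, 2, function(x)
      grDevices::convertColor(matrix(x / 255, 1), "sRGB", "Lab")[1, ]))
    out[[g]] <- data.frame(region = regions, r = rg[1, ], g = rg[2, ], b = rg[3, ],
                           L_star = lab[, 1], a_star = lab[, 2], b_star = lab[, 3],
                           row.names = NULL)
  }
  out
}

#' Configuration for the synthetic study-design generator
#'
#' Defaults emulate the commercial-batch study design this package was built
#' around: 61 batches in 4 latent composition groups (sizes 5/17/21/18),
#' 26 compounds in 4 classes (12 anthraquinones, 5 stilbene glycosides,
#' 4 flavonoids, 5 phenols) with THSG dominating its class, group-linked
#' HepaRG IC50 tiers (A ~540, B ~480, C ~360, D ~420 ug/mL), and
#' group-linked decoction-piece chromaticity.
#'
#' @param n_batches total batches (default 61).
#' @param n_groups latent groups (default 4).
#' @param group_sizes per-group batch counts, summing to `n_batches`.
#' @param compound_means n_groups x 26 matrix of mean concentrations (mg/g).
#' @param compound_cv coefficient of variation of the log-normal concentration
#'   draws (fraction, default 0.22).
#' @param hill_params_by_group list of [hill_params()] per group.
#' @param chroma_means_by_group list (per group) of data.frames with columns
#'   `region, r, g, b, L_star, a_star, b_star`.
#' @param chroma_sd Gaussian SD of site-level channel noise (RGB units).
#' @param noise_sd_viability additive viability noise SD (fraction, 0.05).
#' @param seed master seed; all generators derive their streams from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_batches = 61, n_groups = 4,
                             group_sizes = c(5, 17, 21, 18),
                             compound_means = .default_compound_means(n_groups),
                             compound_cv = 0.22,
                             hill_params_by_group = list(
                               A = hill_params(540, 3), B = hill_params(480, 3),
                               C = hill_params(360, 3), D = hill_params(420, 3)),
                             chroma_means_by_group = .default_chroma_means(n_groups),
                             chroma_sd = 6,
                             noise_sd_viability = 0.05,
                             seed = 1L) {
  if (length(group_sizes) != n_groups)
    .fail("group_sizes has length %d but n_groups is %d", length(group_sizes), n_groups)
  if (sum(group_sizes) != n_batches)
    .fail("group_sizes sum to %d, not n_batches = %d", sum(group_sizes), n_batches)
  if (any(compound_means < 0)) .fail("compound means must be non-negative")
  if (compound_cv < 0) .fail("compound_cv must be non-negative")
  if (noise_sd_viability < 0) .fail("noise_sd_viability must be non-negative")
  stopifnot(nrow(compound_means) == n_groups, ncol(compound_means) == 26,
            length(hill_params_by_group) >= n_groups)
  structure(list(n_batches = n_batches, n_groups = n_groups,
                 group_sizes = group_sizes, compound_means = compound_means,
                 compound_cv = compound_cv,
                 hill_params_by_group = hill_params_by_group,
                 chroma_means_by_group = chroma_means_by_group,
                 chroma_sd = chroma_sd,
                 noise_sd_viability = noise_sd_viability,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Two-group configuration for marker-rule validation
#'
#' A reduced design with only the low- and high-toxicity composition groups
#' and the class difference carried entirely by the two designated marker
#' compounds (EG and THSG); the other 24 compound means are identical across
#' groups, so any additional flag is a false positive by construction.
#' 100 batches per group by default — large enough that the operating
#' characteristics of the conjunction rule (VIP > 1 and q < 0.05) are
#' measurable rather than dominated by the VIP threshold's sampling noise.
#'
#' @param n_per_group batches per group (default 100).
#' @param seed master seed.
#' @param compound_cv concentration CV (default 0.22).
#' @return a [synthetic_config()] with groups relabelled A/B standing in for
#'   the low/high-toxicity pair.
#' @export
synthetic_two_group_config <- function(n_per_group = 100, seed = 1L,
                                       compound_cv = 0.22) {
  m4 <- .default_compound_means(4)
  m <- m4[c("B", "C"), , drop = FALSE]
  m["C", "emodin"] <- m["B", "emodin"]       # only EG + THSG differ
  m["C", "catechin"] <- m["B", "catechin"]
  nm <- setdiff(colnames(m), c("EG", "THSG"))
  m["C", nm] <- m["B", nm]
  rownames(m) <- c("A", "B")
  cm <- .default_chroma_means(4)[c("B", "C")]
  names(cm) <- c("A", "B")
  synthetic_config(n_batches = 2 * n_per_group, n_groups = 2,
                   group_sizes = rep(n_per_group, 2), compound_means = m,
                   compound_cv = compound_cv,
                   hill_params_by_group = list(A = hill_params(480, 3),
                                               B = hill_params(360, 3)),
                   chroma_means_by_group = cm, seed = seed)
}

#' Generate a synthetic batch x compound concentration table
#'
#' Concentrations are drawn log-normally around each group's compound means
#' (log-scale sigma from the CV, mean-preserving), so draws are positive and
#' right-skewed like real quantification data. `compound_cv = 0` reproduces
#' the group means exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return a [compound_table()] with `group` attribute carrying true labels.
#' @export
generate_compound_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  groups <- rep(LETTERS[seq_len(cfg$n_groups)], cfg$group_sizes)
  conc <- matrix(0, cfg$n_batches, 26, dimnames = list(
    sprintf("S%02d", seq_len(cfg$n_batches)), .COMPOUND_IDS))
  sdlog <- sqrt(log(1 + cfg$compound_cv^2))
  .with_seed(derive_seed(cfg$seed, 1L), for (i in seq_len(cfg$n_batches)) {
    mu <- cfg$compound_means[match(groups[i], LETTERS), ]
    if (sdlog == 0) conc[i, ] <- mu
    else conc[i, ] <- stats::rlnorm(26, meanlog = log(pmax(mu, 1e-12)) - sdlog^2 / 2,
                                    sdlog = sdlog) * (mu > 0)
  })
  tab <- compound_table(conc, stats::setNames(.COMPOUND_CLASSES, .COMPOUND_IDS))
  attr(tab, "group") <- stats::setNames(groups, rownames(conc))
  tab
}

#' Generate a synthetic CCK-8 viability plate
#'
#' Absorbance triplets (dosing, blank, control) whose derived viability equals
#' the Hill curve plus additive Gaussian noise truncated at 0. Four replicate
#' wells per dose; blank ~0.1, control ~1.5 absorbance units.
#'
#' @param curve a [hill_params()].
#' @param doses positive dose vector.
#' @param noise_sd viability noise SD (fraction).
#' @param seed integer seed.
#' @param n_replicates wells per dose (default 4).
#' @return data.frame with columns
#'   `dose, replicate, absorbance_dosing, absorbance_blank, absorbance_control`.
#' @export
generate_viability_plate <- function(curve, doses, noise_sd = 0.05, seed = 1L,
                                     n_replicates = 4L) {
  stopifnot(inherits(curve, "hill_params"))
  if (any(doses <= 0)) .fail("doses must be positive")
  if (noise_sd < 0) .fail("noise_sd must be non-negative")
  d <- rep(doses, each = n_replicates)
  v <- .with_seed(derive_seed(seed, 2L),
    pmax(hill_viability(curve, d) + stats::rnorm(length(d), 0, noise_sd), 0))
  blank <- 0.1; control <- 1.5
  data.frame(dose = d, replicate = rep(seq_len(n_replicates), length(doses)),
             absorbance_dosing = blank + v * (control - blank),
             absorbance_blank = blank, absorbance_control = control)
}

#' Generate a synthetic combination ray
#'
#' Observed effects are drawn from the exact Loewe-additive surface of the two
#' single-agent curves ([loewe_effect()]); `interaction = "potency_shift"`
#' multiplies drug 2's effective dose by `shift_factor` before evaluating the
#' surface, injecting synergy (factor > 1) or antagonism (factor < 1).
#' Additive Gaussian noise (percent scale) is truncated into `[0, 100]`.
#'
#' @param curve1,curve2 [hill_params()] single-agent curves.
#' @param dose_pairs two-column matrix/data.frame of positive dose pairs.
#' @param interaction `"loewe_additive"` or `"potency_shift"`.
#' @param shift_factor effective-dose multiplier for drug 2 (potency_shift).
#' @param noise_sd effect noise SD in percent points.
#' @param seed integer seed.
#' @return a [combination_ray()].
#' @export
generate_combination_ray <- function(curve1, curve2, dose_pairs,
                                     interaction = c("loewe_additive", "potency_shift"),
                                     shift_factor = 2, noise_sd = 0, seed = 1L) {
  interaction <- match.arg(interaction)
  dp <- as.matrix(dose_pairs)
  if (any(dp <= 0)) .fail("dose pairs must be positive")
  if (noise_sd < 0) .fail("noise_sd must be non-negative")
  d2eff <- if (interaction == "potency_shift") dp[, 2] * shift_factor else dp[, 2]
  y <- loewe_effect(curve1, curve2, dp[, 1], d2eff)
  if (noise_sd > 0)
    y <- .with_seed(derive_seed(seed, 3L),
                    pmin(pmax(y + stats::rnorm(length(y), 0, noise_sd), 0), 100))
  combination_ray(dp[, 1], dp[, 2], y, curve1, curve2)
}

#' Generate synthetic chromaticity readings
#'
#' Per batch: 4 anatomical regions x 2 surfaces x 5 sites = 40 records, with
#' Gaussian channel noise around the batch group's region means. RGB clamped
#' to `[0, 255]`; CIELAB re-derived per record from the noisy RGB so channels
#' stay mutually consistent.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame of records with columns
#'   `batch_id, region, surface, site, r, g, b, L_star, a_star, b_star`, and a
#'   `group` attribute with true labels.
#' @export
generate_chromaticity <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  groups <- rep(LETTERS[seq_len(cfg$n_groups)], cfg$group_sizes)
  batches <- sprintf("S%02d", seq_len(cfg$n_batches))
  grid <- expand.grid(site = 1:5, surface = c("front", "back"),
                      region = c("cork", "phloem", "central_xylem",
                                 "heteromorphic_bundles"),
                      stringsAsFactors = FALSE)
  out <- vector("list", cfg$n_batches)
  .with_seed(derive_seed(cfg$seed, 4L), for (i in seq_len(cfg$n_batches)) {
    gm <- cfg$chroma_means_by_group[[match(groups[i], LETTERS)]]
    mu <- gm[match(grid$region, gm$region), c("r", "g", "b")]
    rgb <- as.matrix(mu) + matrix(stats::rnorm(nrow(grid) * 3, 0, cfg$chroma_sd),
                                  ncol = 3)
    rgb <- pmin(pmax(rgb, 0), 255)
    lab <- grDevices::convertColor(rgb / 255, "sRGB", "Lab")
    out[[i]] <- data.frame(batch_id = batches[i], region = grid$region,
                           surface = grid$surface, site = grid$site,
                           r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                           L_star = lab[, 1], a_star = lab[, 2], b_star = lab[, 3],
                           stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "group") <- stats::setNames(groups, batches)
  res
}

#' Write a full synthetic bundle to disk
#'
#' Writes the compound table + metadata CSVs, per-group viability plates,
#' the chromaticity CSV, and a JSON sidecar recording the configuration and
#' seed, so a generated study can be re-read through the package's readers.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @param doses dose grid for the viability plates (ug/mL).
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_bundle <- function(cfg, dir,
                                   doses = c(1, 10, 50, 100, 200, 300, 400,
                                             500, 700, 1000)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- generate_compound_table(cfg)
  paths <- list(
    compound_table = file.path(dir, "compound_table.csv"),
    compound_metadata = file.path(dir, "compound_metadata.csv"),
    chromaticity = file.path(dir, "chromaticity.csv"),
    config = file.path(dir, "config.json"))
  write_compound_table(tab, paths$compound_table, paths$compound_metadata)
  grp <- attr(tab, "group")
  utils::write.csv(data.frame(batch_id = names(grp), group = unname(grp)),
                   file.path(dir, "group_labels.csv"), row.names = FALSE)
  for (g in LETTERS[seq_len(cfg$n_groups)]) {
    plate <- generate_viability_plate(cfg$hill_params_by_group[[g]], doses,
                                      cfg$noise_sd_viability,
                                      seed = derive_seed(cfg$seed, 10L + match(g, LETTERS)))
    p <- file.path(dir, sprintf("plate_group_%s.csv", g))
    utils::write.csv(plate, p, row.names = FALSE)
    paths[[paste0("plate_", g)]] <- p
  }
  utils::write.csv(generate_chromaticity(cfg), paths$chromaticity, row.names = FALSE)
  cfg_json <- cfg
  cfg_json$hill_params_by_group <- lapply(cfg$hill_params_by_group, unclass)
  jsonlite::write_json(unclass(cfg_json), paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
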