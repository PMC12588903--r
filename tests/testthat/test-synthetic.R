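test_that("zero-CV compound tables reproduce group means exactly and seeds are reproducible", {
  cfg0 <- synthetic_config(compound_cv = 0, seed = 4)
  tab <- generate_compound_table(cfg0)
  g <- attr(tab, "group")
  for (grp in LETTERS[1:4]) {
    rows <- tab$concentrations[g == grp, , drop = FALSE]
    expect_equal(rows, matrix(cfg0$compound_means[grp, ], nrow(rows), 26,
                              byrow = TRUE, dimnames = dimnames(rows)))
  }
  cfg <- synthetic_config(seed = 7)
  expect_identical(generate_compound_table(cfg), generate_compound_table(cfg))
})

test_that("default composition has dominant THSG and plausible class totals", {
  tab <- generate_compound_table(synthetic_config(seed = 1))
  ct <- class_totals(tab)
  expect_gt(ct$shares$stilbene_glycoside[["THSG"]], 0.9)
  # group A (unqualified) mean THSG sits below the 10 mg/g limit
  g <- attr(tab, "group")
  expect_lt(mean(tab$concentrations[g == "A", "THSG"]), 10)
  expect_true(all(tab$concentrations >= 0))
})

test_that("synthetic config rejects inconsistent sizes and negative noise", {
  expect_error(synthetic_config(n_batches = 10, group_sizes = c(5, 4, 1, 1)),
               "sum")
  expect_error(synthetic_config(group_sizes = c(5, 17, 21)), "length")
  expect_error(generate_viability_plate(hill_params(100, 2), 10, noise_sd = -1),
               "noise_sd")
})

test_that("viability plates follow the Hill curve at zero noise and are seeded", {
  crv <- hill_params(417, 2, floor = 0.1, ceiling = 0.9)
  pl <- generate_viability_plate(crv, c(417, 1e-6), noise_sd = 0, seed = 2)
  v <- viability(pl$absorbance_dosing, pl$absorbance_blank, pl$absorbance_control)
  expect_equal(unique(round(v[pl$dose == 417], 10)),
               0.5 * (0.9 - 0.1) + 0.1)               # midpoint at the IC50
  expect_equal(v[pl$dose == 1e-6], rep(0.9, 4), tolerance = 1e-6)  # ceiling
  expect_true(all(pl$absorbance_blank < pl$absorbance_dosing + 1e-12))
  pl2 <- generate_viability_plate(crv, c(417, 1e-6), noise_sd = 0.05, seed = 9)
  expect_identical(pl2, generate_viability_plate(crv, c(417, 1e-6), 0.05, seed = 9))
})

test_that("Loewe-additive rays are sham-consistent and potency shift injects synergy", {
  cT <- hill_params(417, 3); cE <- hill_params(12.7, 3)
  pairs <- cbind(c(100, 250, 400), c(5, 10, 15))
  ray <- generate_combination_ray(cT, cE, pairs, "loewe_additive", noise_sd = 0)
  res <- predict_additive(ray)
  ci <- combination_index(ray$y_obs, res$f, res$g)
  expect_true(all(abs(ci$ci_d1 - 1) < 1e-6))
  expect_true(all(abs(ci$ci_d2 - 1) < 1e-6))
  shifted <- generate_combination_ray(cT, cE, pairs, "potency_shift",
                                      shift_factor = 2, noise_sd = 0)
  ci2 <- combination_index(shifted$y_obs, res$f, res$g)
  expect_true(all(ci2$ci_d1 > 1) && all(ci2$ci_d2 > 1))
  # self-combination: observed effect equals the single drug at the summed dose
  self_ray <- generate_combination_ray(cT, cT, cbind(150, 150), "loewe_additive",
                                       noise_sd = 0)
  expect_equal(self_ray$y_obs, hill_effect(cT, 300), tolerance = 1e-9)
})

test_that("chromaticity generation has the 4x2x5 design and group-linked color", {
  cfg <- synthetic_config(seed = 3)
  recs <- generate_chromaticity(cfg)
  counts <- table(recs$batch_id)
  expect_true(all(counts == 40))
  expect_true(all(recs$r >= 0 & recs$r <= 255))
  expect_true(all(recs$L_star >= 0 & recs$L_star <= 100))
  # zero noise: every site matches its region mean
  cfg0 <- synthetic_config(seed = 3, chroma_sd = 0)
  r0 <- generate_chromaticity(cfg0)
  one <- r0[r0$batch_id == "S01" & r0$region == "phloem", ]
  expect_equal(unique(round(one$r, 9)),
               cfg0$chroma_means_by_group[["A"]]$r[2])
  # normalized-R group means differ in the constructed direction (C redder than B)
  summ <- batch_color_summaries(recs)
  g <- attr(recs, "group")
  expect_gt(mean(summ$norm_r[g[summ$batch_id] == "C"]),
            mean(summ$norm_r[g[summ$batch_id] == "B"]))
})

test_that("zero-noise generation inverts: Hill fits recover generator parameters", {
  crv <- hill_params(417, 2)
  doses <- c(1, 10, 50, 100, 200, 300, 400, 500, 700, 1000)
  pl <- generate_viability_plate(crv, doses, noise_sd = 0, seed = 5)
  v <- viability(pl$absorbance_dosing, pl$absorbance_blank, pl$absorbance_control)
  fit <- fit_hill(pl$dose, v)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$ic50 - 417) / 417, 1e-6)
  expect_lt(abs(fit$params$slope - 2) / 2, 1e-6)
})

test_that("a written synthetic bundle can be re-read through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 11)
  paths <- write_synthetic_bundle(cfg, dir)
  tab <- read_compound_table(paths$compound_table, paths$compound_metadata)
  expect_s3_class(tab, "compound_table")
  expect_equal(dim(tab$concentrations), c(61, 26))
  expect_true(file.exists(paths$config))
  plate <- utils::read.csv(paths$plate_B)
  expect_true(all(c("dose", "absorbance_dosing", "absorbance_blank",
                    "absorbance_control") %in% names(plate)))
})
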