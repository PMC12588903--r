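curve_T <- hill_params(417.0, 3)
curve_E <- hill_params(12.7, 3)

test_that("equivalent-dose conversion is exact for Hill curves", {
  crv <- hill_params(200, 2.5)
  expect_equal(equivalent_dose(crv, crv, c(0, 10, 200, 900)), c(0, 10, 200, 900),
               tolerance = 1e-10)
  # iso-effect at 50%: the other drug's IC50 maps onto the target's IC50
  expect_equal(equivalent_dose(curve_T, curve_E, 12.7), 417.0, tolerance = 1e-9)
  expect_equal(equivalent_dose(curve_E, curve_T, 417.0), 12.7, tolerance = 1e-9)
  # equal-slope curves convert by the IC50 ratio at every dose
  expect_equal(equivalent_dose(curve_T, curve_E, 5), 5 * 417 / 12.7,
               tolerance = 1e-9)
  # inversion round-trip reproduces the other curve's effect
  set.seed(30)
  for (i in 1:25) {
    a <- hill_params(runif(1, 5, 500), runif(1, 0.5, 4))
    b <- hill_params(runif(1, 5, 500), runif(1, 0.5, 4))
    d <- runif(1, 0.1, 800)
    eq <- equivalent_dose(a, b, d)
    expect_equal(hill_effect(a, eq), hill_effect(b, d), tolerance = 1e-6)
  }
  # saturation: effect above the target's attainable inhibition -> infinite dose
  shallow <- hill_params(100, 2, floor = 0.5)   # cannot exceed 50% inhibition
  expect_equal(equivalent_dose(shallow, curve_T, 1e6), Inf)
})

test_that("additive predictions match a brute-force inversion oracle", {
  ray <- combination_ray(350, 12.5, 92.13, curve_T, curve_E,
                         drug_names = c("THSG", "EG"))
  add <- predict_additive(ray)
  eq1 <- grid_hill_inverse(curve_T, hill_effect(curve_E, 12.5))
  eq2 <- grid_hill_inverse(curve_E, hill_effect(curve_T, 350))
  expect_equal(add$f, hill_effect(curve_T, 350 + eq1), tolerance = 1e-6)
  expect_equal(add$g, hill_effect(curve_E, 12.5 + eq2), tolerance = 1e-6)
  expect_equal(add$belt_lo, min(add$f, add$g))
  # identical curves at a symmetric pair: sham combination, f = g = curve(2d)
  sham <- predict_additive(combination_ray(100, 100, 50, curve_T, curve_T))
  expect_equal(sham$f, hill_effect(curve_T, 200), tolerance = 1e-9)
  expect_equal(sham$g, sham$f, tolerance = 1e-9)
})

test_that("combination indices reproduce the reference rows and handle zeros", {
  ci <- combination_index(92.13, 56.91, 92.59)
  expect_equal(round_half_up(ci$ci_d1, 4), 1.6189)
  expect_equal(round_half_up(ci$ci_d2, 4), 0.9950)
  zero <- combination_index(0, 8.03, 9.62)
  expect_equal(zero$ci_d1, 0)
  expect_equal(zero$ci_d2, 0)
  expect_error(combination_index(-1, 50, 50), "non-negative")
})

test_that("interaction judgments follow the pattern rule with a strict alternative", {
  expect_equal(judge_interaction(1.2862, 1.0494), "synergistic")
  expect_equal(judge_interaction(1.6180, 0.8775), "additive")
  expect_equal(judge_interaction(0, 0), "antagonistic")
  expect_equal(judge_interaction(1.0, 1.0), "antagonistic")     # boundary: <= 1
  expect_equal(judge_interaction(1.618, 0.8775, mode = "strict"), NA_character_)
  expect_equal(judge_interaction(0.5, 0.9, mode = "strict"), "antagonistic")
  expect_error(judge_interaction(-0.1, 0.5), "non-negative")
})

test_that("the packaged reference table reproduces its CI and judgment columns", {
  tab <- read_combination_table(system.file("extdata", "table2_thsg_eg.csv",
                                            package = "pmtox"))
  expect_equal(nrow(tab), 10)
  out <- combination_table_ci(tab)
  # all ten judgments follow from the published CI pair under the pattern rule
  expect_equal(judge_interaction(tab$ci_d1_reported, tab$ci_d2_reported),
               tab$judgment_reported)
  # recomputed CI agrees with the published values to within one unit in the
  # fourth decimal everywhere (the published table was rounded upstream)
  expect_lte(max(abs(out$ci_d1 - tab$ci_d1_reported)), 1e-4 + 1e-12)
  expect_lte(max(abs(out$ci_d2 - tab$ci_d2_reported)), 1e-4 + 1e-12)
})

test_that("analyze_ray reports rounded tables, order-equivariantly", {
  pairs <- cbind(c(250, 350, 450), c(7.5, 12.5, 17.5))
  ray <- generate_combination_ray(curve_T, curve_E, pairs, "potency_shift",
                                  shift_factor = 2, noise_sd = 0)
  res <- analyze_ray(ray)
  expect_named(res, c("dose_drug1", "dose_drug2", "f", "g", "y_obs",
                      "ci_d1", "ci_d2", "judgment"))
  expect_true(all(res$judgment == "synergistic"))
  rev_ray <- combination_ray(rev(ray$dose1), rev(ray$dose2), rev(ray$y_obs),
                             curve_T, curve_E)
  res_rev <- analyze_ray(rev_ray)
  expect_equal(res_rev[nrow(res_rev):1, ], res, ignore_attr = TRUE)
  # additive belt attribute brackets both predictions
  belt <- attr(res, "belt")
  expect_true(all(belt$lo <= belt$hi))
})

test_that("exact Loewe surfaces are sham-consistent for any dose split", {
  set.seed(31)
  for (i in 1:20) {
    crv <- hill_params(runif(1, 10, 500), runif(1, 0.5, 4),
                       floor = runif(1, 0, 0.15), ceiling = runif(1, 0.85, 1))
    total <- runif(1, 0.2, 4) * crv$ic50
    frac <- runif(1, 0.05, 0.95)
    y <- loewe_effect(crv, crv, total * frac, total * (1 - frac))
    expect_equal(y, hill_effect(crv, total), tolerance = 1e-6)
  }
})
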