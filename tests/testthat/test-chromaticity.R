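test_that("E*ab and normalized RGB identities hold exactly", {
  expect_equal(e_ab(3, 0, 4), 5)
  expect_equal(e_ab(0, 0, 0), 0)
  expect_equal(e_ab(62.3, 0, 0), 62.3)
  expect_equal(e_ab(50, 10, -20), e_ab(50, -10, 20))   # sign-blind by design

  expect_equal(unlist(normalize_rgb(100, 100, 100)), rep(1 / 3, 3),
               ignore_attr = TRUE)
  expect_equal(unlist(normalize_rgb(255, 0, 0)), c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(unlist(normalize_rgb(120, 60, 20)), c(0.6, 0.3, 0.1),
               ignore_attr = TRUE)
  expect_error(normalize_rgb(0, 0, 0), "positive")
  set.seed(40)
  for (i in 1:20) {
    x <- runif(3, 1, 255)
    n1 <- normalize_rgb(x[1], x[2], x[3])
    expect_equal(sum(n1), 1, tolerance = 1e-10)
    expect_equal(n1, normalize_rgb(2 * x[1], 2 * x[2], 2 * x[3]))  # scale-free
  }
})

make_records <- function(batch = "S1", r = 100, g = 90, b = 80, n_regions = 4) {
  grid <- expand.grid(site = 1:5, surface = c("front", "back"),
                      region = c("cork", "phloem", "central_xylem",
                                 "heteromorphic_bundles")[seq_len(n_regions)],
                      stringsAsFactors = FALSE)
  lab <- grDevices::convertColor(matrix(c(r, g, b) / 255, 1), "sRGB", "Lab")
  data.frame(batch_id = batch, grid, r = r, g = g, b = b,
             L_star = lab[1], a_star = lab[2], b_star = lab[3],
             stringsAsFactors = FALSE)
}

test_that("batch aggregation takes hierarchical means and flags incompleteness", {
  recs <- make_records()
  s <- aggregate_batch(recs)
  expect_equal(c(s$mean_r, s$mean_g, s$mean_b), c(100, 90, 80))
  expect_false(s$incomplete)
  expect_true(aggregate_batch(recs[-1, ])$incomplete)
  expect_error(aggregate_batch(rbind(recs, recs[1, ])), "duplicate")
  # balanced design with two region levels: grand mean of the region means
  two <- make_records()
  two$r <- ifelse(two$region %in% c("cork", "phloem"), 100, 200)
  expect_equal(aggregate_batch(two)$mean_r, 150)
})

test_that("derived quantities come from batch means in the documented order", {
  recs <- make_records()
  s <- aggregate_batch(recs)
  expect_equal(s$e_ab, e_ab(s$mean_L, s$mean_a, s$mean_b_star))
  expect_equal(s$norm_r + s$norm_g + s$norm_b, 1, tolerance = 1e-10)
})

test_that("IC50 regression on normalized channels recovers exact and null cases", {
  set.seed(41)
  n <- 30
  rgb <- matrix(runif(3 * n, 50, 200), n)
  summaries <- do.call(rbind, lapply(seq_len(n), function(i)
    aggregate_batch(make_records(sprintf("S%02d", i), rgb[i, 1], rgb[i, 2],
                                 rgb[i, 3]))))
  ic50 <- 100 + 1000 * summaries$norm_b
  names(ic50) <- summaries$batch_id
  # exact linear relation: lm warns about the perfect fit, by design here
  reg <- suppressWarnings(color_toxicity_regression(summaries, ic50))
  b_row <- reg[reg$channel == "norm_b", ]
  expect_equal(b_row$slope, 1000, tolerance = 1e-8)
  expect_equal(b_row$r_squared, 1, tolerance = 1e-8)

  # channel independent of IC50: slope p-value exceeds 0.05 in >= 90% of sims
  set.seed(42)
  null_p <- vapply(1:100, function(i) {
    x <- runif(100); y <- rnorm(100)
    summary(stats::lm(y ~ x))$coefficients[2, 4]
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.9)
})

test_that("group-linked synthetic color recovers the injected sign structure", {
  cfg <- synthetic_config(seed = 43)
  recs <- generate_chromaticity(cfg)
  summ <- batch_color_summaries(recs)
  truth <- attr(recs, "group")
  ic50_by_group <- vapply(cfg$hill_params_by_group, `[[`, numeric(1), "ic50")
  ic50 <- stats::setNames(ic50_by_group[match(truth[summ$batch_id],
                                              names(ic50_by_group))],
                          summ$batch_id)
  reg <- color_toxicity_regression(summ, ic50)
  expect_gt(reg$slope[reg$channel == "norm_b"], 0)
  expect_lt(reg$slope[reg$channel == "norm_r"], 0)
})

test_that("color clustering separates constructed groups and co-clusters duplicates", {
  cfg <- synthetic_config(seed = 44)
  recs <- generate_chromaticity(cfg)
  summ <- batch_color_summaries(recs)
  truth <- attr(recs, "group")[summ$batch_id]
  keep <- truth %in% c("B", "C", "D")
  res <- color_hca(summ[keep, ], k = 3)
  expect_gte(pair_count_ari(res$labels, truth[keep]), 0.9)
  one <- summ[keep, ][c(1, 1, 30, 30), ]
  one$batch_id <- c("X1", "X2", "Y1", "Y2")
  res_dup <- color_hca(one, k = 2)
  expect_equal(res_dup$labels[["X1"]], res_dup$labels[["X2"]]) # duplicates together
  expect_equal(unname(color_hca(summ[1:2, ], k = 1)$labels), c(1, 1))
})

test_that("image extraction reproduces reference CIELAB values", {
  gray <- array(128 / 255, c(4, 4, 3))
  res <- extract_from_image(gray)
  expect_equal(unname(res$lab[["L_star"]]), 53.6, tolerance = 0.5)
  expect_lt(abs(res$lab[["a_star"]]), 0.5)
  expect_lt(abs(res$lab[["b_star"]]), 0.5)

  white <- array(1, c(2, 2, 3))
  resw <- extract_from_image(white)
  expect_equal(unname(resw$lab[["L_star"]]), 100, tolerance = 1e-6)
  expect_equal(unname(resw$mean_rgb), rep(255, 3))

  img <- array(runif(5 * 6 * 3), c(5, 6, 3))
  px <- extract_from_image(img, crop_box = c(2, 2, 3, 3))
  expect_equal(unname(px$mean_rgb), img[2, 3, ] * 255, tolerance = 1e-10)
  expect_equal(px$n_pixels, 1)
  expect_error(extract_from_image(img, crop_box = c(3, 2, 1, 1)), "empty")
  expect_error(extract_from_image(img, crop_box = c(1, 9, 1, 2)), "bounds")

  # PNG round trip through the file reader
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(c(0.2, 0.5, 0.8), c(1, 1, 3)), f)
  resf <- extract_from_image(f)
  expect_equal(unname(resf$mean_rgb) / 255, c(0.2, 0.5, 0.8), tolerance = 0.01)
})
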