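# Chromaticity descriptors of decoction pieces: hierarchical aggregation of
# per-site readings, E*ab, normalized RGB, color-based clustering, and
# per-channel regression against IC50.

#' Overall color parameter E*ab
#'
#' \eqn{E^*_{ab} = \sqrt{L^{*2} + a^{*2} + b^{*2}}}. Note the squares make
#' E*ab blind to the sign of a*/b* (a red and a green cast of equal chroma
#' coincide) — a property of the descriptor itself.
#'
#' @param L_star,a_star,b_star CIELAB coordinates.
#' @return non-negative numeric.
#' @export
e_ab <- function(L_star, a_star, b_star) sqrt(L_star^2 + a_star^2 + b_star^2)

#' Intensity-invariant normalized RGB
#'
#' Each channel divided by the channel sum; components sum to 1 and are
#' invariant to a common gain.
#'
#' @param r,g,b channel values with `r + g + b > 0`.
#' @return data.frame with `norm_r, norm_g, norm_b`.
#' @export
normalize_rgb <- function(r, g, b) {
  s <- r + g + b
  if (any(s <= 0)) .fail("r + g + b must be positive")
  data.frame(norm_r = r / s, norm_g = g / s, norm_b = b / s)
}

#' Aggregate one batch's chromaticity records into a batch summary
#'
#' Hierarchical means: sites within region x surface, then regions within
#' surface, then the two surfaces — equivalent to the grand mean under the
#' complete balanced 4 x 2 x 5 design. Derived quantities (E*ab, normalized
#' RGB) are computed from the batch-mean channels, not per record. A summary
#' built from fewer than the full 40 records is flagged `incomplete`.
#'
#' @param records data.frame with columns
#'   `batch_id, region, surface, site, r, g, b, L_star, a_star, b_star` for a
#'   single batch.
#' @return one-row data.frame (class `batch_color_summary`).
#' @export
aggregate_batch <- function(records) {
  if (length(unique(records$batch_id)) != 1)
    .fail("aggregate_batch expects records for exactly one batch")
  key <- with(records, paste(region, surface, site))
  if (anyDuplicated(key)) .fail("duplicate (region, surface, site) cell: %s",
                                key[duplicated(key)][1])
  chans <- c("r", "g", "b", "L_star", "a_star", "b_star")
  # site -> region x surface means, then region -> surface, then surfaces
  m1 <- stats::aggregate(records[chans],
                         by = records[c("region", "surface")], FUN = mean)
  m2 <- stats::aggregate(m1[chans], by = m1["surface"], FUN = mean)
  mu <- colMeans(m2[chans])
  nr <- normalize_rgb(mu[["r"]], mu[["g"]], mu[["b"]])
  out <- data.frame(batch_id = records$batch_id[1],
                    mean_r = mu[["r"]], mean_g = mu[["g"]], mean_b = mu[["b"]],
                    mean_L = mu[["L_star"]], mean_a = mu[["a_star"]],
                    mean_b_star = mu[["b_star"]],
                    e_ab = e_ab(mu[["L_star"]], mu[["a_star"]], mu[["b_star"]]),
                    norm_r = nr$norm_r, norm_g = nr$norm_g, norm_b = nr$norm_b,
                    incomplete = nrow(records) < 40,
                    stringsAsFactors = FALSE)
  class(out) <- c("batch_color_summary", class(out))
  out
}

#' Batch color summaries for a full set of records
#'
#' @param records chromaticity records for any number of batches.
#' @return data.frame, one [aggregate_batch()] row per batch.
#' @export
batch_color_summaries <- function(records) {
  out <- do.call(rbind, lapply(split(records, records$batch_id), aggregate_batch))
  rownames(out) <- NULL
  out[order(out$batch_id), , drop = FALSE]
}

#' Regress IC50 on each normalized color channel
#'
#' Ordinary least squares of IC50 against `norm_r`, `norm_g`, `norm_b`
#' separately (univariate per channel), with the two-sided slope p-value.
#'
#' @param summaries output of [batch_color_summaries()].
#' @param ic50 named vector, batch id -> IC50 (ug/mL).
#' @return data.frame `channel, slope, intercept, r_squared, p_value`.
#' @export
color_toxicity_regression <- function(summaries, ic50) {
  common <- intersect(summaries$batch_id, names(ic50))
  if (length(common) < 3) .fail("need at least 3 batches with IC50 values")
  s <- summaries[match(common, summaries$batch_id), ]
  y <- ic50[common]
  do.call(rbind, lapply(c("norm_r", "norm_g", "norm_b"), function(ch) {
    x <- s[[ch]]
    if (stats::sd(x) < .Machine$double.eps^0.5)
      .fail("channel %s is constant; slope undefined", ch)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(channel = ch,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               stringsAsFactors = FALSE)
  }))
}

#' Cluster batches by color descriptors
#'
#' Delegates to [hca()] on autoscaled
#' `(norm_r, norm_g, norm_b, mean_L, mean_a, mean_b_star, e_ab)` features.
#'
#' @param summaries output of [batch_color_summaries()].
#' @param k clusters (default 3).
#' @param linkage,metric passed to [hca()].
#' @return [hca()] result with `labels` named by batch id.
#' @export
color_hca <- function(summaries, k = 3, linkage = "ward", metric = "euclidean") {
  feats <- as.matrix(summaries[, c("norm_r", "norm_g", "norm_b", "mean_L",
                                   "mean_a", "mean_b_star", "e_ab")])
  rownames(feats) <- summaries$batch_id
  res <- hca(autoscale(feats), linkage = linkage, metric = metric, k = k)
  names(res$labels) <- summaries$batch_id
  res
}

#' Mean RGB and CIELAB of an image crop
#'
#' Accepts a numeric array (`height x width x 3`, values in `[0, 1]` or
#' 0-255) or a path to a PNG/TIFF file. The crop is given as
#' `c(row1, row2, col1, col2)` (inclusive); `NULL` means the whole image.
#' CIELAB uses the sRGB working space with D65 white point and the 2-degree
#' observer (the common image-editing default).
#'
#' @param image array or file path.
#' @param crop_box integer vector `c(row1, row2, col1, col2)` or `NULL`.
#' @return list with `mean_rgb` (0-255 scale), `lab`
#'   (`L_star, a_star, b_star`), and `n_pixels`.
#' @export
extract_from_image <- function(image, crop_box = NULL) {
  if (is.character(image)) {
    ext <- tolower(tools::file_ext(image))
    image <- switch(ext,
                    png = png::readPNG(image),
                    tif = , tiff = tiff::readTIFF(image),
                    .fail("unsupported image format: .%s", ext))
  }
  if (length(dim(image)) == 2) image <- array(rep(image, 3), c(dim(image), 3))
  if (dim(image)[3] > 3) image <- image[, , 1:3, drop = FALSE]
  if (max(image) > 1) image <- image / 255
  if (!is.null(crop_box)) {
    if (crop_box[1] > crop_box[2] || crop_box[3] > crop_box[4])
      .fail("empty crop box")
    if (crop_box[1] < 1 || crop_box[2] > dim(image)[1] ||
        crop_box[3] < 1 || crop_box[4] > dim(image)[2])
      .fail("crop box outside image bounds")
    image <- image[crop_box[1]:crop_box[2], crop_box[3]:crop_box[4], ,
                   drop = FALSE]
  }
  mu <- apply(image, 3, mean)
  lab <- grDevices::convertColor(matrix(mu, 1), "sRGB", "Lab")[1, ]
  list(mean_rgb = mu * 255,
       lab = c(L_star = lab[[1]], a_star = lab[[2]], b_star = lab[[3]]),
       n_pixels = prod(dim(image)[1:2]))
}
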