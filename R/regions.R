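#' Subtract the autofluorescence channel from the marker channel
#'
#' Autofluorescent material appears in both the green (marker) and red
#' channels, true tracer only in green, so a brightness-matched pixelwise
#' subtraction `green - scale * red` cancels autofluorescence while leaving
#' tracer intact. The channels are first brought to a common brightness
#' scale: `scale` is the ratio of median green to median red intensity over
#' red-foreground pixels (red above its median + 6 MAD), which compensates
#' unequal exposure times without being dragged by background or by
#' green-only tracer. If the red channel has no appreciable foreground the
#' scale is 1. Negative differences are clipped to 0 (the corrected image
#' feeds a threshold on positive signal).
#'
#' @param green,red numeric matrices of equal shape.
#' @param equalize logical; set `FALSE` to skip brightness matching
#'   (scale fixed at 1).
#' @return corrected numeric matrix with attribute `brightness_scale`.
#' @export
correct_autofluorescence <- function(green, red, equalize = TRUE) {
  if (!all(dim(green) == dim(red))) abort("green and red shapes differ")
  scale <- 1
  if (equalize) {
    medr <- median(red)
    madr <- stats::mad(red)
    fg <- red > medr + 6 * madr
    if (sum(fg) >= 10 && median(red[fg]) > 0)
      scale <- median(green[fg]) / median(red[fg])
  }
  out <- pmax(green - scale * red, 0)
  attr(out, "brightness_scale") <- scale
  out
}

#' Count tracer pixels in an autofluorescence-corrected image
#'
#' Otsu-binarizes the corrected marker channel and counts pixels above the
#' threshold. Because Otsu always splits a histogram — even one containing
#' only background noise — the threshold is accepted only if it clears a
#' noise floor (background mean + `k_floor` background standard deviations,
#' background being the below-threshold class). If it does not, the image is
#' declared signal-free: pixels above the noise floor are counted instead
#' (essentially zero), with a warning. A constant image yields count 0 with
#' a degenerate-threshold warning.
#'
#' @param corrected numeric matrix from [correct_autofluorescence()].
#' @param node_class optional label (`"DCLN-left"`, `"DCLN-right"`,
#'   `"SCLN"`, `"ILN"`).
#' @param k_floor noise-floor multiplier (default 6).
#' @return a tibble with columns `node_class`, `pixel_count`, `threshold`,
#'   `method`.
#' @export
count_tracer_pixels <- function(corrected, node_class = NA_character_,
                                k_floor = 6) {
  v <- as.vector(corrected)
  if (length(unique(v)) < 2) {
    warn("degenerate (constant) corrected image; count 0")
    return(tibble(node_class = node_class, pixel_count = 0L,
                  threshold = NA_real_, method = "degenerate"))
  }
  thr <- otsu_threshold(tabulate_intensities(v))
  # noise floor from robust quantiles: after clipped subtraction the
  # background is max(N(0, sigma), 0), whose 90th percentile sits at
  # 1.2816 sigma above the median; signal occupying < 10% of pixels cannot
  # perturb the estimate
  sigma_hat <- (quantile(v, 0.90, names = FALSE) - median(v)) / 1.2816
  floor_t <- median(v) + k_floor * sigma_hat
  if (thr >= floor_t) {
    tibble(node_class = node_class, pixel_count = sum(v > thr),
           threshold = thr, method = "otsu")
  } else {
    warn("Otsu threshold below the noise floor; image treated as signal-free")
    tibble(node_class = node_class, pixel_count = sum(v > floor_t),
           threshold = floor_t, method = "noise-floor")
  }
}

#' Region mask set for vessel-vs-parenchyma intensity measurements
#'
#' @param vessel,tissue,artifact logical matrices of equal shape; pairwise
#'   disjoint. Artifact pixels are excluded from every measurement.
#' @return an object of class `region_mask_set`.
#' @export
region_mask_set <- function(vessel, tissue, artifact = NULL) {
  if (is.null(artifact)) artifact <- matrix(FALSE, nrow(vessel), ncol(vessel))
  stopifnot(all(dim(vessel) == dim(tissue)),
            all(dim(vessel) == dim(artifact)))
  if (any(vessel & tissue) || any(vessel & artifact) || any(tissue & artifact))
    abort("region masks must be pairwise disjoint")
  structure(list(vessel = vessel, tissue = tissue, artifact = artifact),
            class = "region_mask_set")
}

#' Normalized per-region intensity
#'
#' Sums the image intensity over each region's non-artifact pixels and
#' divides by the region area — the normalized intensity is a mean intensity
#' per pixel (reported also per um^2 if `pixel_um` is given).
#'
#' @param image numeric matrix.
#' @param masks a [region_mask_set()].
#' @param image_id,group identifying labels carried into the result.
#' @param pixel_um optional pixel size for areas in um^2.
#' @return a tibble with one row per region: `image_id`, `group`, `region`,
#'   `area_px`, `area_um2`, `total_intensity`, `normalized_intensity`.
#' @export
normalized_region_intensity <- function(image, masks, image_id = NA_character_,
                                        group = NA_character_,
                                        pixel_um = NA_real_) {
  stopifnot(inherits(masks, "region_mask_set"),
            all(dim(image) == dim(masks$vessel)))
  one <- function(region, m) {
    m <- m & !masks$artifact
    if (!any(m)) abort(sprintf("region '%s' is empty after artifact exclusion",
                               region))
    tibble(image_id = image_id, group = group, region = region,
           area_px = sum(m),
           area_um2 = if (is.na(pixel_um)) NA_real_ else sum(m) * pixel_um^2,
           total_intensity = sum(image[m]),
           normalized_intensity = sum(image[m]) / sum(m))
  }
  dplyr::bind_rows(one("vessel", masks$vessel), one("tissue", masks$tissue))
}

#' Paired vessel-vs-tissue intensity comparison
#'
#' Pairs the vessel and surrounding-tissue normalized intensities within
#' each image, checks the paired differences for normality (Shapiro-Wilk)
#' and runs the paired t-test on vessel minus tissue. The reported estimate
#' is the mean difference. Group-level aggregation across images (e.g. a
#' living vs. sacrificed contrast of the differences) should use
#' [mann_whitney_u()] on the per-image differences; note that despite its
#' occasional billing as a paired test it is an unpaired test, and it is
#' applied here to independent per-image values.
#'
#' @param results a tibble as returned by rows of
#'   [normalized_region_intensity()] over several images.
#' @return a list of class `region_comparison`: `pairs` (tibble with one row
#'   per image: vessel, tissue, difference), `normality` (a `test_outcome`),
#'   `t_test` (a `test_outcome`).
#' @export
paired_region_comparison <- function(results) {
  stopifnot(all(c("image_id", "region", "normalized_intensity")
                %in% names(results)))
  wide <- results |>
    dplyr::select("image_id", "region", "normalized_intensity") |>
    tidyr::pivot_wider(names_from = "region",
                       values_from = "normalized_intensity")
  if (!all(c("vessel", "tissue") %in% names(wide)))
    abort("need both 'vessel' and 'tissue' regions")
  wide <- wide[!is.na(wide$vessel) & !is.na(wide$tissue), ]
  if (nrow(wide) < 3) abort("need at least 3 paired (vessel, tissue) values")
  diffs <- wide$vessel - wide$tissue
  if (sd(diffs) == 0) abort("zero-variance differences: degenerate pairing")
  normality <- test_normality(diffs, method = "shapiro-wilk")
  tt <- paired_t_test(wide$vessel, wide$tissue)
  structure(list(pairs = dplyr::mutate(wide, difference = diffs),
                 normality = normality, t_test = tt),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("Paired vessel vs tissue comparison over %d images\n",
              nrow(x$pairs)))
  cat(sprintf("mean difference (vessel - tissue): %.4f\n",
              mean(x$pairs$difference)))
  print(x$normality)
  print(x$t_test)
  invisible(x)
}

#' @rdname paired_region_comparison
#' @param x a `region_comparison`.
#' @param ... unused.
#' @export
tidy.region_comparison <- function(x, ...) {
  tibble(method = c(x$normality$method, x$t_test$method),
         statistic = c(x$normality$statistic, x$t_test$statistic),
         p.value = c(x$normality$p_value, x$t_test$p_value),
         estimate = c(NA_real_, x$t_test$estimate))
}
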