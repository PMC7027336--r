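#' Intensity histogram of a raster
#'
#' @param x numeric vector, matrix or array of intensities.
#' @return a tibble with columns `value` (sorted unique intensities) and
#'   `count`.
#' @export
tabulate_intensities <- function(x) {
  v <- as.vector(x)
  v <- v[!is.na(v)]
  tb <- table(v)
  tibble(value = as.numeric(names(tb)), count = as.integer(tb))
}

#' Otsu's threshold from an intensity histogram
#'
#' Returns the threshold `t` maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2` of the classes `{value <= t}` and `{value > t}`
#' (cluster variance maximization). Candidate thresholds are the observed
#' intensity values except the largest (which would leave the upper class
#' empty); ties are broken by the smallest `t`.
#'
#' @param histogram a tibble/data frame with columns `value` and `count`
#'   (as from [tabulate_intensities()]), or a named numeric vector of counts
#'   with intensity values as names.
#' @return the threshold value.
#' @export
otsu_threshold <- function(histogram) {
  if (is.numeric(histogram) && !is.null(names(histogram)))
    histogram <- tibble(value = as.numeric(names(histogram)),
                        count = as.numeric(histogram))
  stopifnot(all(c("value", "count") %in% names(histogram)))
  h <- histogram[histogram$count > 0, ]
  h <- h[order(h$value), ]
  k <- nrow(h)
  if (k < 2) abort("degenerate histogram: fewer than 2 distinct intensities")
  n <- sum(h$count)
  w0 <- cumsum(h$count) / n                 # P(value <= t) at t = value[i]
  mu <- cumsum(h$value * h$count) / n       # partial means (unnormalized)
  mu_tot <- mu[k]
  i <- seq_len(k - 1)
  sb <- (mu_tot * w0[i] - mu[i])^2 / (w0[i] * (1 - w0[i]))
  h$value[which.max(sb)]                    # which.max takes the first = smallest t
}

#' Binary tracer-positive volume
#'
#' Thresholds the tracer channel of a volume: a voxel is positive iff its
#' intensity is strictly greater than the threshold AND it lies inside the
#' brain mask. With `threshold = "auto"` the threshold is Otsu's method on
#' the masked intensity histogram; pass a number for a manual override.
#'
#' @param volume a [volume_grid()].
#' @param channel channel to binarize (default `"tracer"`).
#' @param threshold `"auto"` (Otsu) or a numeric value.
#' @return an object of class `binary_volume`: fields `positive` (logical
#'   array), `spacing`, `mask`, `threshold`, `method`.
#' @export
binarize_tracer <- function(volume, channel = "tracer", threshold = "auto") {
  stopifnot(inherits(volume, "volume_grid"))
  if (!channel %in% names(volume$channels)) abort("unknown channel")
  arr <- volume$channels[[channel]]
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(tabulate_intensities(arr[volume$mask]))
    method <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    thr <- threshold
    method <- "manual"
  }
  structure(list(positive = (arr > thr) & volume$mask,
                 spacing = volume$spacing, mask = volume$mask,
                 threshold = thr, method = method),
            class = "binary_volume")
}

#' Construct a binary volume directly (phantom/testing route)
#' @param positive logical 3-D array of positive voxels.
#' @param spacing voxel spacing `(axial, row, col)`, micrometres.
#' @param mask brain mask; defaults to all-TRUE.
#' @param threshold,method provenance fields.
#' @export
binary_volume <- function(positive, spacing, mask = NULL, threshold = NA,
                          method = "direct") {
  if (is.null(mask)) mask <- array(TRUE, dim(positive))
  stopifnot(length(dim(positive)) == 3, all(dim(mask) == dim(positive)),
            length(spacing) == 3, all(spacing > 0))
  positive <- positive & mask
  structure(list(positive = positive, spacing = as.numeric(spacing),
                 mask = mask, threshold = threshold, method = method),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s voxels, %d positive (threshold %s, %s)\n",
              paste(dim(x$positive), collapse = " x "), sum(x$positive),
              format(x$threshold), x$method))
  invisible(x)
}

#' Count tracer-positive voxels
#' @param binary a `binary_volume`.
#' @return integer count.
#' @export
count_positive_voxels <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  sum(binary$positive)
}

#' Vertical hemisphere separation polyline at a given column
#'
#' Convenience constructor for the common case of a straight midline.
#' @param col column coordinate of the separation plane.
#' @param n_rows number of rows the polyline must span.
#' @return a tibble with columns `vertex_row`, `vertex_col`.
#' @export
midline_polyline <- function(col, n_rows) {
  tibble(vertex_row = c(1, n_rows), vertex_col = c(col, col))
}

#' Split positive voxels into hemispheres
#'
#' The separation surface is a 2-D polyline in registered pixel coordinates
#' (ordered vertices `(vertex_row, vertex_col)` spanning the full row
#' extent), extruded through all slices — the volumetric reading of a
#' separation line drawn once on a projection. Each positive voxel is
#' classified by the signed side of the surface at its row: columns smaller
#' than the interpolated polyline column are `left`, larger are `right`,
#' equal are `on_surface` (reported separately so the count conservation is
#' exact). The ipsilateral hemisphere is named by `ipsi_side`.
#'
#' @param binary a `binary_volume`.
#' @param separation a data frame with columns `vertex_row`, `vertex_col`
#'   (one polyline used for every slice) or `slice_index`, `vertex_row`,
#'   `vertex_col` for per-slice polylines.
#' @param ipsi_side `"left"` or `"right"`: which side holds the injection
#'   site.
#' @return a tibble with one row: `ipsi`, `contra`, `on_surface`, `total`.
#' @export
split_hemispheres <- function(binary, separation, ipsi_side = c("left", "right")) {
  stopifnot(inherits(binary, "binary_volume"))
  ipsi_side <- match.arg(ipsi_side)
  stopifnot(all(c("vertex_row", "vertex_col") %in% names(separation)))
  per_slice <- "slice_index" %in% names(separation)
  d <- dim(binary$positive)

  boundary_col <- function(poly, rows) {
    poly <- poly[order(poly$vertex_row), ]
    if (min(poly$vertex_row) > 1 || max(poly$vertex_row) < d[2])
      abort("separation polyline does not span the full row extent")
    approx(poly$vertex_row, poly$vertex_col, xout = rows, ties = "ordered")$y
  }

  idx <- which(binary$positive, arr.ind = TRUE)   # (slice, row, col)
  n_left <- 0L; n_right <- 0L; n_on <- 0L
  if (nrow(idx) > 0) {
    slices <- if (per_slice) sort(unique(idx[, 1])) else NA
    if (per_slice) {
      for (s in slices) {
        poly <- separation[separation$slice_index == s, ]
        if (nrow(poly) < 2)
          abort(sprintf("no separation polyline for slice %d", s))
        sub <- idx[idx[, 1] == s, , drop = FALSE]
        bc <- boundary_col(poly, sub[, 2])
        n_left <- n_left + sum(sub[, 3] < bc)
        n_right <- n_right + sum(sub[, 3] > bc)
        n_on <- n_on + sum(sub[, 3] == bc)
      }
    } else {
      bc <- boundary_col(separation, idx[, 2])
      n_left <- sum(idx[, 3] < bc)
      n_right <- sum(idx[, 3] > bc)
      n_on <- sum(idx[, 3] == bc)
    }
  }
  ipsi <- if (ipsi_side == "left") n_left else n_right
  contra <- if (ipsi_side == "left") n_right else n_left
  tibble(ipsi = as.integer(ipsi), contra = as.integer(contra),
         on_surface = as.integer(n_on),
         total = as.integer(nrow(idx)))
}
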