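#' Volumetric multichannel grid
#'
#' The reconstructed dataset: one 3-D raster per channel on a common
#' anisotropic grid, with a brain mask. Array axis order is
#' `(slice, row, col)`; `spacing` is `(axial, row, col)` in micrometres.
#'
#' @param channels named list of numeric 3-D arrays of equal shape.
#' @param spacing numeric length-3, micrometres per voxel along each axis;
#'   strictly positive.
#' @param mask logical array, same shape as the channels.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(channels, spacing, mask) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  shp <- dim(channels[[1]])
  for (ch in channels) stopifnot(length(dim(ch)) == 3, all(dim(ch) == shp))
  stopifnot(length(spacing) == 3, all(spacing > 0), all(dim(mask) == shp))
  structure(list(channels = channels, spacing = as.numeric(spacing),
                 mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ (%g, %g, %g) um, channels: %s; %d masked voxels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(names(x$channels), collapse = ", "), sum(x$mask)))
  invisible(x)
}

# 6-connected flood fill from a logical seed set, constrained to `domain`;
# vectorized frontier dilation, in-plane only if axial = FALSE
flood_fill3d <- function(domain, seeds, axial = TRUE) {
  reached <- seeds & domain
  shift_or <- function(m) {
    d <- dim(m); out <- array(FALSE, d)
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    if (axial && d[1] > 1) {
      out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
      out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    }
    out
  }
  repeat {
    grown <- reached | (shift_or(reached) & domain)
    if (sum(grown) == sum(reached)) break
    reached <- grown
  }
  reached
}

# largest 6-connected component of a logical array
largest_component3d <- function(bin) {
  best <- array(FALSE, dim(bin)); best_n <- 0
  remaining <- bin
  while (any(remaining)) {
    seed_idx <- which(remaining)[1]
    seeds <- array(FALSE, dim(bin)); seeds[seed_idx] <- TRUE
    comp <- flood_fill3d(remaining, seeds)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  best
}

# fill in-plane holes: background connected to the slice border stays
# background, enclosed background becomes mask
fill_holes_slicewise <- function(bin) {
  d <- dim(bin)
  border <- array(FALSE, d)
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- flood_fill3d(!bin, border & !bin, axial = FALSE)
  bin | (!bin & !outside)
}

#' Assemble a registered slice stack into a volumetric dataset
#'
#' Stacks each channel along the axial axis and derives the brain mask from
#' the nuclei channel: global Otsu threshold, largest 6-connected component,
#' then per-slice hole filling (vessels, ventricles and staining gaps inside
#' tissue belong to the brain volume for distance purposes).
#'
#' @param stack a registered [slice_stack()].
#' @param mask_channel channel used for mask derivation (default `"nuclei"`).
#' @return a [volume_grid()] with spacing `(axial_um, in_plane_um,
#'   in_plane_um)`.
#' @export
assemble_volume <- function(stack, mask_channel = "nuclei") {
  stopifnot(inherits(stack, "slice_stack"), mask_channel %in% stack$channels)
  channels <- lapply(stack$channels, function(ch) stack$data[, , , ch])
  names(channels) <- stack$channels
  nuc <- channels[[mask_channel]]
  thr <- otsu_threshold(tabulate_intensities(nuc))
  bin <- nuc > thr
  m <- fill_holes_slicewise(largest_component3d(bin))
  volume_grid(channels,
              spacing = c(stack$axial_um, stack$in_plane_um,
                          stack$in_plane_um),
              mask = m)
}

#' Maximum intensity projection along an anatomical axis
#'
#' For a stack of horizontal sections the array axes map to anatomy as:
#' axis 1 (slice) = dorsoventral, axis 2 (row) = anteroposterior, axis 3
#' (col) = mediolateral. Hence `"horizontal"` projects along the axial/slice
#' index, `"coronal"` along rows, `"sagittal"` along columns.
#'
#' @param volume a [volume_grid()].
#' @param axis `"coronal"`, `"sagittal"` or `"horizontal"`.
#' @param channel channel name (default `"tracer"`).
#' @return a numeric matrix of per-ray maxima.
#' @export
maximum_projection <- function(volume, axis, channel = "tracer") {
  stopifnot(inherits(volume, "volume_grid"))
  if (!channel %in% names(volume$channels)) abort("unknown channel")
  arr <- volume$channels[[channel]]
  ax <- switch(axis,
               horizontal = 1L, coronal = 2L, sagittal = 3L,
               abort(sprintf("unknown projection axis '%s'", axis)))
  apply(arr, setdiff(1:3, ax), max)
}
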