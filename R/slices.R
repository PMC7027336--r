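#' Ordered multichannel slice stack
#'
#' The in-memory form of a serial-section export: an ordered set of
#' equally-shaped 2-D multichannel rasters with their physical spacing.
#' Stored as a 4-D array `(slice, row, col, channel)` with named channels;
#' intensities live on the 0-1 scale.
#'
#' @param data numeric 4-D array `(slice, row, col, channel)`.
#' @param channels character vector naming the channels (e.g. `"nuclei"`,
#'   `"tracer"`).
#' @param in_plane_um,axial_um physical spacing in micrometres.
#' @return an object of class `slice_stack`.
#' @export
slice_stack <- function(data, channels, in_plane_um, axial_um) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] == length(channels),
            in_plane_um > 0, axial_um > 0)
  dimnames(data) <- list(NULL, NULL, NULL, channels)
  structure(list(data = data, channels = channels,
                 in_plane_um = in_plane_um, axial_um = axial_um),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<slice_stack> %d slices of %d x %d px, channels: %s, spacing %g/%g um\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "),
              x$in_plane_um, x$axial_um))
  invisible(x)
}

n_slices <- function(stack) dim(stack$data)[1]

#' Extract one channel plane of one slice as a matrix
#' @param stack a `slice_stack`.
#' @param slice slice index (1-based).
#' @param channel channel name.
#' @export
slice_plane <- function(stack, slice, channel) {
  stopifnot(channel %in% stack$channels)
  stack$data[slice, , , channel]
}

# separable Gaussian smoothing (reflect padding), used for texture grain
smooth2d <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1]))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

# shared nuclei texture: base level, coarse Gaussian blobs and a fine
# cellular grain, identical for every slice so neighboring sections look
# alike (as real DAPI-stained tissue does). The grain gives the texture the
# high-frequency content that makes in-plane rotation sharply identifiable.
nuclei_texture <- function(spec) {
  nr <- spec$shape[2]; nc <- spec$shape[3]
  local_seed(spec$seed * 13 + 7, {
    k <- 18
    cy <- runif(k, 1, nr); cx <- runif(k, 1, nc)
    s <- runif(k, 0.04, 0.12) * max(nr, nc)
    a <- runif(k, 0.1, 0.35)
    tex <- matrix(0.35, nr, nc)
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(k))
      tex <- tex + a[i] * exp(-((yy - cy[i])^2 + (xx - cx[i])^2) / (2 * s[i]^2))
    grain <- smooth2d(matrix(runif(nr * nc, -1, 1), nr, nc), sigma = 1.2)
    grain <- grain / sd(grain)
    pmin(pmax(tex + 0.12 * grain, 0.05), 1)
  })
}

#' Render a tracer field into a misaligned multichannel slice stack
#'
#' Sections the 3-D field into per-slice images the way the slide-scanner
#' exports look: a nuclei channel (brain-mask texture), a tracer channel
#' (the field scaled to 0-1 by its global maximum), per-slice multiplicative
#' brightness jitter on the nuclei channel, an independent zero-mean rigid
#' misalignment per slice, additive Gaussian noise and optional 8-bit
#' quantization. The applied transforms and the noise-free truth are
#' recorded in the ground-truth object.
#'
#' @param field numeric array `(slices, rows, cols)` from a tracer simulator.
#' @param spec the `phantom_spec` that produced `field`.
#' @return a list with elements `stack` (a [slice_stack()]) and `truth`, a
#'   `phantom_truth` list carrying `transforms` (applied per-slice
#'   misalignments), `field`, `mask`, `positive_threshold` (0-1 scale; one
#'   8-bit half-step), `positive_count` (voxels above it), and
#'   `hemisphere_counts` (named: ipsi, contra) at the same threshold.
#' @export
render_slices <- function(field, spec) {
  if (!all(dim(field) == spec$shape)) abort("field shape mismatch with spec")
  mask <- brain_mask(spec)
  ns <- spec$shape[1]
  tex <- nuclei_texture(spec)
  fmax <- max(field)
  tracer_scaled <- if (fmax > 0) field / fmax else field

  local_seed(spec$seed * 17 + 3, {
    trunc_norm <- function(n, sd, bound) {
      if (sd == 0) return(rep(0, n))
      x <- rnorm(n, sd = sd)
      while (any(bad <- abs(x) > bound)) x[bad] <- rnorm(sum(bad), sd = sd)
      x
    }
    ang <- trunc_norm(ns, spec$misalign_sigma_deg, spec$misalign_max_deg)
    dxs <- trunc_norm(ns, spec$misalign_sigma_px, spec$misalign_max_px)
    dys <- trunc_norm(ns, spec$misalign_sigma_px, spec$misalign_max_px)
    bright <- if (spec$brightness_jitter > 0)
      runif(ns, 1 - spec$brightness_jitter, 1 + spec$brightness_jitter)
    else rep(1, ns)

    dat <- array(0, c(spec$shape, 2))
    transforms <- vector("list", ns)
    for (k in seq_len(ns)) {
      tf <- rigid_transform(ang[k], dxs[k], dys[k])
      transforms[[k]] <- tf
      nuc <- tex * mask[k, , ] * bright[k]
      tra <- tracer_scaled[k, , ]
      dat[k, , , 1] <- apply_transform(nuc, tf, fill = 0)
      dat[k, , , 2] <- apply_transform(tra, tf, fill = 0)
    }
    if (spec$noise_sigma > 0)
      dat <- dat + rnorm(length(dat), sd = spec$noise_sigma)
    dat <- pmin(pmax(dat, 0), 1)
    if (spec$quantize) dat <- round(dat * 255) / 255

    thr <- 0.5 / 255
    pos <- tracer_scaled > thr & mask
    mid <- phantom_midline(spec)
    cols <- slice.index(pos, 3)
    ipsi_left <- spec$injection[3] < mid
    left <- sum(pos & cols < mid); right <- sum(pos & cols > mid)
    hemi <- if (ipsi_left) c(ipsi = left, contra = right)
            else c(ipsi = right, contra = left)

    truth <- structure(list(
      transforms = transforms, field = field, mask = mask,
      positive_threshold = thr, positive_count = sum(pos),
      hemisphere_counts = hemi, spec = spec
    ), class = "phantom_truth")

    list(stack = slice_stack(dat, c("nuclei", "tracer"),
                             spec$in_plane_um, spec$axial_um),
         truth = truth)
  })
}

#' Generate a full phantom (field + rendered stack + ground truth)
#'
#' Convenience wrapper: simulates the tracer field of `spec` and renders it.
#' @param spec a `phantom_spec`.
#' @return as [render_slices()], plus element `field`.
#' @export
generate_phantom <- function(spec) {
  field <- simulate_tracer(spec)
  out <- render_slices(field, spec)
  out$field <- field
  out
}

#' Generate a synthetic lymph-node image with ground truth
#'
#' A three-channel raster emulating a cryosection scan: tracer particles
#' bright in green only, autofluorescent particles equally bright in green
#' and red, nuclei texture in blue. Particles are discs placed without
#' overlap inside an elliptical node mask by rejection sampling. Per-class
#' pixel counts are exact ground truth for the autofluorescence-correction
#' and counting stages.
#'
#' @param n_tracer,n_autofluor particle counts (>= 0).
#' @param radius_px particle radius in pixels.
#' @param shape image `(rows, cols)`; default 96 x 96 px at 0.65 um/px.
#' @param pixel_um pixel size, micrometres.
#' @param amplitude particle brightness (0-1 scale).
#' @param background background level in green and red.
#' @param noise_sigma additive Gaussian noise (0-1 scale).
#' @param max_tries rejection-sampling retries before giving up.
#' @param seed integer seed.
#' @return list with `image` (array `(row, col, channel)`, channels
#'   `red`, `green`, `blue`) and `truth` (list: `tracer_pixels`,
#'   `autofluor_pixels`, per-particle centers).
#' @export
generate_lymphnode_image <- function(n_tracer, n_autofluor, radius_px = 3,
                                     shape = c(96L, 96L), pixel_um = 0.65,
                                     amplitude = 0.8, background = 0.05,
                                     noise_sigma = 0.02, max_tries = 5000,
                                     seed = 1L) {
  stopifnot(n_tracer >= 0, n_autofluor >= 0, radius_px >= 1)
  nr <- shape[1]; nc <- shape[2]
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  node <- ((yy - rc) / (0.45 * nr))^2 + ((xx - cc) / (0.45 * nc))^2 < 1

  local_seed(seed, {
    n_total <- n_tracer + n_autofluor
    centers <- matrix(0, 0, 2)
    tries <- 0
    while (nrow(centers) < n_total) {
      tries <- tries + 1
      if (tries > max_tries)
        abort("could not place all particles without overlap; reduce counts or radius")
      # integer-centered discs: every particle renders the same pixel set
      # shape, so per-class pixel counts are exact multiples of disc area
      cand <- c(sample(seq(radius_px + 1, nr - radius_px), 1),
                sample(seq(radius_px + 1, nc - radius_px), 1))
      if (!node[cand[1], cand[2]]) next
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) <= 2 * radius_px + 1)
        next
      centers <- rbind(centers, cand)
    }

    disc_mask <- function(ctr) (yy - ctr[1])^2 + (xx - ctr[2])^2 <= radius_px^2
    green <- matrix(background, nr, nc)
    red <- matrix(background, nr, nc)
    tracer_px <- matrix(FALSE, nr, nc)
    auto_px <- matrix(FALSE, nr, nc)
    idx_tracer <- seq_len(n_tracer)
    for (i in seq_len(n_total)) {
      d <- disc_mask(centers[i, ])
      green[d] <- background + amplitude
      if (i %in% idx_tracer) tracer_px <- tracer_px | d
      else { red[d] <- background + amplitude; auto_px <- auto_px | d }
    }
    blue <- 0.3 * node + 0.1
    img <- array(0, c(nr, nc, 3))
    img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
    if (noise_sigma > 0)
      img <- img + rnorm(length(img), sd = noise_sigma)
    img <- pmin(pmax(img, 0), 1)
    dimnames(img) <- list(NULL, NULL, c("red", "green", "blue"))

    list(image = img,
         truth = list(tracer_pixels = sum(tracer_px),
                      autofluor_pixels = sum(auto_px),
                      centers = centers, radius_px = radius_px,
                      pixel_um = pixel_um))
  })
}
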