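#' Estimate the rigid transform aligning one slice onto another
#'
#' Finds the rotation + translation that, applied to `moving`
#' ([apply_transform()] convention), best matches `fixed` under normalized
#' cross-correlation (NCC). NCC is invariant to linear intensity changes, so
#' the estimate is insensitive to the per-slice brightness drift that
#' [equalize_brightness()] corrects. The search is a coarse-to-fine pyramid:
#' exhaustive angle x integer-shift search at the coarsest level, local grid
#' refinement per level, then continuous Nelder-Mead refinement at full
#' resolution for subpixel/subdegree accuracy. Fully deterministic.
#'
#' @param fixed,moving numeric matrices of equal shape with nonconstant
#'   intensity.
#' @param max_shift_px,max_angle_deg search bounds.
#' @param presmooth_sigma Gaussian pre-smoothing (pixels) applied to both
#'   images before correlation. Resampling the moving image blurs it
#'   slightly; correlating a blurred candidate against a pristine fixed
#'   image biases the rotation estimate by ~0.1-0.2 degrees, and matching
#'   the blur on both sides removes that bias. 0 disables.
#' @return a `rigid_transform2d` `tf` such that `apply_transform(moving, tf)`
#'   is aligned with `fixed`, with attribute `ncc` (achieved correlation).
#' @export
estimate_rigid_transform <- function(fixed, moving, max_shift_px = 24,
                                     max_angle_deg = 12,
                                     presmooth_sigma = 0.8) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)))
  if (sd(fixed) == 0 || sd(moving) == 0)
    abort("uninformative content: constant image")
  if (presmooth_sigma > 0) {
    fixed <- smooth2d(fixed, presmooth_sigma)
    moving <- smooth2d(moving, presmooth_sigma)
  }

  # correlation support: interior (eroded) foreground of the fixed image.
  # Restricting NCC to interior tissue excludes the tissue/background
  # boundary, where neighboring sections genuinely differ (the section
  # outline changes slice to slice) and which otherwise biases the estimate
  # by a few tenths of a pixel per pair. Falls back to all pixels when no
  # usable foreground exists (e.g. texture-only images).
  erode <- function(m, k) {
    d <- dim(m)
    for (j in seq_len(k)) {
      out <- m
      out[-1, ] <- out[-1, ] & m[-d[1], ]
      out[-d[1], ] <- out[-d[1], ] & m[-1, ]
      out[, -1] <- out[, -1] & m[, -d[2]]
      out[, -d[2]] <- out[, -d[2]] & m[, -1]
      m <- out
    }
    m
  }
  support <- tryCatch({
    fg <- erode(fixed > otsu_threshold(tabulate_intensities(fixed)), 4)
    if (sum(fg) >= 200) fg else array(TRUE, dim(fixed))
  }, error = function(e) array(TRUE, dim(fixed)))

  ncc <- function(a, b, sup) {
    ok <- sup & !is.na(b)
    if (sum(ok) < 16) return(-Inf)
    av <- a[ok]; bv <- b[ok]
    if (sd(av) == 0 || sd(bv) == 0) return(-Inf)
    cor(av, bv)
  }
  score <- function(lv, angle, dx, dy)
    ncc(lv$fixed, .warp_rigid_cpp(lv$moving, angle, dx, dy, NA_real_),
        lv$support)

  downsample <- function(img) {
    nr <- floor(nrow(img) / 2) * 2; nc <- floor(ncol(img) / 2) * 2
    img <- img[seq_len(nr), seq_len(nc)]
    0.25 * (img[seq(1, nr, 2), seq(1, nc, 2)] +
            img[seq(2, nr, 2), seq(1, nc, 2)] +
            img[seq(1, nr, 2), seq(2, nc, 2)] +
            img[seq(2, nr, 2), seq(2, nc, 2)])
  }

  # build pyramid (level 1 = full resolution)
  pyr <- list(list(fixed = fixed, moving = moving, support = support))
  while (min(dim(pyr[[length(pyr)]]$fixed)) >= 32 && length(pyr) < 4) {
    lv <- pyr[[length(pyr)]]
    pyr[[length(pyr) + 1]] <- list(fixed = downsample(lv$fixed),
                                   moving = downsample(lv$moving),
                                   support = downsample(lv$support) > 0.75)
  }

  nlev <- length(pyr)
  # exhaustive search at the coarsest level
  lv <- pyr[[nlev]]
  fac <- 2^(nlev - 1)
  ms <- ceiling(max_shift_px / fac) + 1
  angles <- seq(-max_angle_deg, max_angle_deg, by = max(0.5, max_angle_deg / 8))
  best <- c(angle = 0, dx = 0, dy = 0); best_s <- -Inf
  for (a in angles) {
    rot <- .warp_rigid_cpp(lv$moving, a, 0, 0, NA_real_)
    for (dy in -ms:ms) for (dx in -ms:ms) {
      s <- ncc(lv$fixed, .warp_rigid_cpp(rot, 0, dx, dy, NA_real_),
               lv$support)
      if (s > best_s) { best_s <- s; best <- c(angle = a, dx = dx, dy = dy) }
    }
  }

  # refine down the pyramid: local grids around the upscaled estimate
  if (nlev > 1) for (l in (nlev - 1):1) {
    lv <- pyr[[l]]
    best["dx"] <- best["dx"] * 2; best["dy"] <- best["dy"] * 2
    astep <- max(0.25, max_angle_deg / 8 / 2^(nlev - l))
    best_s <- -Inf; b <- best
    for (a in best["angle"] + astep * (-1:1))
      for (dy in best["dy"] + (-2:2)) for (dx in best["dx"] + (-2:2)) {
        s <- score(lv, a, dx, dy)
        if (s > best_s) { best_s <- s; b <- c(angle = a, dx = dx, dy = dy) }
      }
    best <- b
  }

  # continuous refinement at full resolution
  obj <- function(p) -score(pyr[[1]], p[1], p[2], p[3])
  opt <- optim(unname(best), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 400,
                              parscale = c(0.5, 1, 1)))
  out <- rigid_transform(opt$par[1], opt$par[2], opt$par[3])
  attr(out, "ncc") <- -opt$value
  out
}

#' Rigidly register a slice stack
#'
#' Sequential pairwise registration on one channel, propagated outward from a
#' reference slice (default: the middle of the stack, which halves the
#' worst-case accumulation of pairwise errors compared to anchoring at the
#' first slice). Each slice's cumulative transform is the composition of the
#' pairwise estimates linking it to the reference; all channels of a slice
#' are resampled with the same transform (bilinear interpolation).
#'
#' @param stack a [slice_stack()].
#' @param channel channel used for the similarity estimate (default
#'   `"nuclei"`: morphology is present in every slice, tracer is not).
#' @param reference reference slice index; default `ceiling(n/2)`.
#' @param ... passed to [estimate_rigid_transform()].
#' @return list with `stack` (registered) and `transforms` (per-slice
#'   cumulative `rigid_transform2d`, identity at the reference).
#' @export
register_stack <- function(stack, channel = "nuclei", reference = NULL, ...) {
  stopifnot(inherits(stack, "slice_stack"), channel %in% stack$channels)
  n <- n_slices(stack)
  if (n < 2) abort("need at least 2 slices to register")
  ref <- reference %||% ceiling(n / 2)

  pairwise <- function(i, j) {   # transform mapping slice i onto slice j
    tryCatch(
      estimate_rigid_transform(slice_plane(stack, j, channel),
                               slice_plane(stack, i, channel), ...),
      error = function(e)
        abort(sprintf("registration failed for slice pair (%d, %d): %s",
                      i, j, conditionMessage(e)))
    )
  }

  cum <- vector("list", n)
  cum[[ref]] <- rigid_transform(0, 0, 0)
  if (ref < n) for (i in (ref + 1):n)
    cum[[i]] <- compose_transform(cum[[i - 1]], pairwise(i, i - 1))
  if (ref > 1) for (i in (ref - 1):1)
    cum[[i]] <- compose_transform(cum[[i + 1]], pairwise(i, i + 1))

  dat <- stack$data
  for (i in seq_len(n)) {
    if (is_identity_transform(cum[[i]])) next
    for (ch in stack$channels)
      dat[i, , , ch] <- apply_transform(stack$data[i, , , ch], cum[[i]],
                                        fill = 0)
  }
  list(stack = slice_stack(dat, stack$channels, stack$in_plane_um,
                           stack$axial_um),
       transforms = cum)
}

#' Equalize per-slice brightness of one channel
#'
#' Linearly rescales each slice of the chosen channel so that its foreground
#' mean matches the stack-wide median of foreground means, compensating the
#' exposure/mounting drift between separately scanned slides. Foreground is
#' the slice's own Otsu split of that channel (scale-invariant, so the
#' correction is well-defined for arbitrarily mis-scaled slices). Other
#' channels are untouched; output is clipped to [0, 1]. A slice whose
#' foreground mean is zero is left unscaled with a warning.
#'
#' @param stack a [slice_stack()].
#' @param channel channel to equalize (default `"nuclei"`).
#' @return a `slice_stack` with the channel rescaled.
#' @export
equalize_brightness <- function(stack, channel = "nuclei") {
  stopifnot(inherits(stack, "slice_stack"), channel %in% stack$channels)
  n <- n_slices(stack)
  means <- numeric(n)
  for (i in seq_len(n)) {
    pl <- slice_plane(stack, i, channel)
    fg <- tryCatch(pl > otsu_threshold(tabulate_intensities(pl)),
                   error = function(e) matrix(FALSE, nrow(pl), ncol(pl)))
    means[i] <- if (any(fg)) mean(pl[fg]) else 0
  }
  target <- median(means[means > 0])
  dat <- stack$data
  for (i in seq_len(n)) {
    if (means[i] == 0) {
      warn(sprintf("slice %d has zero foreground mean; left unscaled", i))
      next
    }
    dat[i, , , channel] <- pmin(pmax(stack$data[i, , , channel] *
                                       (target / means[i]), 0), 1)
  }
  slice_stack(dat, stack$channels, stack$in_plane_um, stack$axial_um)
}
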