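#' Phantom specification for synthetic serial-section data
#'
#' Defines the geometry, transport model and corruption model of a synthetic
#' brain phantom. The acquisition geometry defaults mirror horizontal
#' vibratome sections scanned at low magnification: 70 um slice thickness and
#' 10.4 um in-plane pixels; the grid covers a field of view around the
#' injection site rather than a whole brain, so downstream statistics run at
#' desk scale.
#'
#' Two transport modes are provided. `"diffusive"` evaluates the 3-D
#' point-source diffusion Green's function (tracer confined near the
#' injection site, as in non-vital tissue). `"advective"` deposits tracer
#' along a branching vessel/fiber-tract skeleton reaching the contralateral
#' hemisphere (the vital pattern). Neither is a physiological model; they are
#' minimal fields reproducing the two qualitative spread patterns with exact
#' ground truth.
#'
#' @param shape integer vector `(slices, rows, cols)` of the voxel grid.
#' @param in_plane_um in-plane pixel size, micrometres.
#' @param axial_um slice thickness, micrometres.
#' @param injection voxel coordinates `(slice, row, col)` (1-based) of the
#'   injection center; default: mid-slice, mid-row, centered in the left
#'   hemisphere. Must fall inside the brain mask.
#' @param mode `"diffusive"` or `"advective"`.
#' @param D diffusion coefficient, um^2/min. The default (300) makes the
#'   30-min diffusion length `sqrt(4 D t)` about 190 um, a sixth of the
#'   default in-plane field of view.
#' @param t_min elapsed time since injection, minutes.
#' @param mass total tracer mass (arbitrary units).
#' @param reach_um advective mode: target skeleton arclength from the
#'   injection site, micrometres; also the arclength decay constant.
#' @param deposit_um advective mode: Gaussian tube radius (sigma) around the
#'   skeleton, micrometres.
#' @param misalign_sigma_px,misalign_sigma_deg per-slice rigid misalignment
#'   scales (zero-mean normal draws, truncated at `misalign_max_px` /
#'   `misalign_max_deg`).
#' @param misalign_max_px,misalign_max_deg hard truncation bounds for the
#'   misalignment draws.
#' @param noise_sigma additive Gaussian intensity noise (on the 0-1 scale).
#' @param brightness_jitter per-slice multiplicative brightness factor drawn
#'   uniformly from `1 +/- brightness_jitter` (emulates exposure drift that
#'   brightness equalization must undo).
#' @param quantize logical; quantize rendered slices to 8-bit levels.
#' @param seed integer seed; the seed fully determines every generated
#'   artifact.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(20L, 96L, 96L),
                         in_plane_um = 10.4,
                         axial_um = 70,
                         injection = NULL,
                         mode = c("diffusive", "advective"),
                         D = 300,
                         t_min = 30,
                         mass = 1,
                         reach_um = 700,
                         deposit_um = 25,
                         misalign_sigma_px = 3,
                         misalign_sigma_deg = 1.5,
                         misalign_max_px = 10,
                         misalign_max_deg = 5,
                         noise_sigma = 0.02,
                         brightness_jitter = 0.15,
                         quantize = TRUE,
                         seed = 1L) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 2))
    abort("shape must be three integers >= 2 (slices, rows, cols)")
  if (in_plane_um <= 0 || axial_um <= 0) abort("spacings must be > 0")
  if (t_min < 0) abort("t_min must be >= 0")
  if (mode == "diffusive" && D <= 0) abort("D must be > 0 for diffusive mode")
  if (is.null(injection))
    injection <- c(ceiling(shape[1] / 2), ceiling(shape[2] / 2),
                   round(shape[3] * 0.3))
  injection <- as.integer(injection)
  spec <- structure(list(
    shape = shape, in_plane_um = in_plane_um, axial_um = axial_um,
    injection = injection, mode = mode, D = D, t_min = t_min, mass = mass,
    reach_um = reach_um, deposit_um = deposit_um,
    misalign_sigma_px = misalign_sigma_px,
    misalign_sigma_deg = misalign_sigma_deg,
    misalign_max_px = misalign_max_px, misalign_max_deg = misalign_max_deg,
    noise_sigma = noise_sigma, brightness_jitter = brightness_jitter,
    quantize = quantize, seed = as.integer(seed)
  ), class = "phantom_spec")
  m <- brain_mask(spec)
  if (!m[injection[1], injection[2], injection[3]])
    abort("injection center must lie inside the brain mask")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d voxels @ (%g, %g, %g) um, mode = %s, seed = %d\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$axial_um, x$in_plane_um, x$in_plane_um, x$mode, x$seed))
  invisible(x)
}

#' Voxel spacing of a phantom, `(axial, row, col)` in micrometres
#' @param spec a `phantom_spec`.
#' @export
phantom_spacing <- function(spec) {
  c(spec$axial_um, spec$in_plane_um, spec$in_plane_um)
}

#' Brain mask of a phantom
#'
#' A stack of coaxial ellipses forming an ellipsoid, with a narrow notch cut
#' along the midline in the upper rows of every slice (a stylized
#' longitudinal fissure). The notch makes the hemisphere split unambiguous:
#' the midline column plane separates left (ipsilateral by default) from
#' right.
#'
#' @param spec a `phantom_spec`.
#' @return logical array `(slices, rows, cols)`.
#' @export
brain_mask <- function(spec) {
  ns <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  zc <- (ns + 1) / 2; rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  az <- 0.85 * ns; ar <- 0.42 * nr; ac <- 0.45 * nc
  z <- (seq_len(ns) - zc) / az
  r <- (seq_len(nr) - rc) / ar
  cl <- (seq_len(nc) - cc) / ac
  # in-plane ellipse radius shrinks toward the first/last slice
  shrink <- sqrt(pmax(0, 1 - z^2))
  m <- array(FALSE, spec$shape)
  r2 <- outer(r^2, cl^2, `+`)        # (row, col) squared ellipse radius
  for (k in seq_len(ns)) {
    if (shrink[k] <= 0) next
    m[k, , ] <- r2 < shrink[k]^2
  }
  # midline notch: remove a 1-2 px wide furrow in the upper (anterior) rows
  notch <- abs(seq_len(nc) - cc) <= max(1, round(nc * 0.01))
  upper <- seq_len(floor(nr * 0.45))
  m[, upper, notch] <- FALSE
  m
}

#' Midline column of a phantom grid
#'
#' Columns strictly below this value belong to the left hemisphere (the
#' default injection side), columns above to the right.
#' @param spec a `phantom_spec`.
#' @export
phantom_midline <- function(spec) (spec$shape[3] + 1) / 2

#' Generate a branching vessel/fiber-tract skeleton
#'
#' Grows a main path from the injection site across the midline into the
#' contralateral hemisphere plus a few side branches, as a biased random walk
#' on the voxel grid constrained to the brain mask. Arclength from the
#' injection site is tracked in physical units and drives the tracer decay in
#' advective mode. Deterministic given `spec$seed`.
#'
#' @param spec a `phantom_spec`.
#' @return a tibble with columns `branch`, `z`, `y`, `x` (1-based voxel
#'   coordinates) and `arclength_um`, ordered along each branch.
#' @export
generate_vessel_tree <- function(spec) {
  mask <- brain_mask(spec)
  if (!any(mask)) abort("degenerate brain mask: no interior voxels")
  sp <- phantom_spacing(spec)
  mid <- phantom_midline(spec)
  contra_right <- spec$injection[3] < mid   # walk toward +col if injected left

  local_seed(spec$seed * 7 + 101, {
    step_walk <- function(start, bias, length_um, arc0) {
      pos <- start
      out <- list(c(pos, arc0))
      arc <- arc0
      guard <- 0
      while (arc - arc0 < length_um && guard < 10 * length_um) {
        guard <- guard + 1
        # candidate unit step: biased direction + isotropic wander
        dirn <- bias + rnorm(3, sd = c(0.25, 0.6, 0.35))
        stp <- sign(round(dirn / max(abs(dirn))))   # -1/0/1 per axis
        if (all(stp == 0)) next
        cand <- pos + stp
        if (any(cand < 1) || any(cand > spec$shape) ||
            !mask[cand[1], cand[2], cand[3]]) next
        arc <- arc + sqrt(sum((stp * sp)^2))
        pos <- cand
        out[[length(out) + 1]] <- c(pos, arc)
      }
      do.call(rbind, out)
    }

    col_bias <- if (contra_right) 1.2 else -1.2
    main <- step_walk(spec$injection, c(0, 0, col_bias), spec$reach_um, 0)
    branches <- list(main)
    n_side <- 3L
    if (nrow(main) > 4) {
      picks <- unique(round(seq(2, nrow(main) - 1, length.out = n_side)))
      for (p in picks) {
        bias <- c(rnorm(1, sd = 0.4), sample(c(-1, 1), 1) * 0.9,
                  rnorm(1, sd = 0.4))
        branches[[length(branches) + 1]] <-
          step_walk(main[p, 1:3], bias, spec$reach_um * 0.35, main[p, 4])
      }
    }
    tab <- do.call(rbind, lapply(seq_along(branches), function(i)
      cbind(branch = i, branches[[i]])))
    tibble(branch = as.integer(tab[, 1]), z = as.integer(tab[, 2]),
           y = as.integer(tab[, 3]), x = as.integer(tab[, 4]),
           arclength_um = tab[, 5])
  })
}

#' Simulate a diffusive ("sacrificed") tracer field
#'
#' Evaluates the free-space point-source diffusion Green's function
#' `c(r, t) = M (4 pi D t)^(-3/2) exp(-r^2 / (4 D t))` at voxel centers in
#' physical coordinates, masks it to the brain and renormalizes so the masked
#' field integrates (sum times voxel volume) to the total mass `M`. At
#' `t = 0` the whole mass sits in the injection voxel.
#'
#' @param spec a `phantom_spec` with `mode = "diffusive"`.
#' @return numeric array `(slices, rows, cols)`; concentration in mass per
#'   um^3.
#' @export
simulate_diffusive_tracer <- function(spec) {
  if (spec$mode != "diffusive") abort("spec$mode must be 'diffusive'")
  mask <- brain_mask(spec)
  sp <- phantom_spacing(spec)
  vox_vol <- prod(sp)
  f <- array(0, spec$shape)
  if (spec$t_min == 0) {
    f[spec$injection[1], spec$injection[2], spec$injection[3]] <-
      spec$mass / vox_vol
    return(f)
  }
  s2 <- 4 * spec$D * spec$t_min
  dz <- (seq_len(spec$shape[1]) - spec$injection[1]) * sp[1]
  dy <- (seq_len(spec$shape[2]) - spec$injection[2]) * sp[2]
  dx <- (seq_len(spec$shape[3]) - spec$injection[3]) * sp[3]
  r2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  f <- spec$mass * (pi * s2)^(-1.5) * exp(-r2 / s2)
  f[!mask] <- 0
  f * (spec$mass / (sum(f) * vox_vol))
}

#' Simulate an advective ("living") tracer field
#'
#' Deposits tracer as a Gaussian tube of radius `deposit_um` around the
#' vessel skeleton, with amplitude decaying exponentially in arclength from
#' the injection site (decay constant `reach_um`), plus a small diffusive
#' component at the injection site (10% of the mass, emulating local leakage
#' at the damaged injection track). The field is masked to the brain and
#' normalized to total mass `M`.
#'
#' @param spec a `phantom_spec` with `mode = "advective"`.
#' @param skeleton optional precomputed [generate_vessel_tree()] output.
#' @return numeric array `(slices, rows, cols)`.
#' @export
simulate_advective_tracer <- function(spec, skeleton = NULL) {
  if (spec$mode != "advective") abort("spec$mode must be 'advective'")
  if (is.null(skeleton)) skeleton <- generate_vessel_tree(spec)
  if (nrow(skeleton) == 0) abort("empty vessel skeleton")
  mask <- brain_mask(spec)
  sp <- phantom_spacing(spec)
  f <- array(0, spec$shape)
  w <- spec$deposit_um
  half <- pmax(1L, ceiling(3 * w / sp))   # 3-sigma box per axis, voxels
  for (i in seq_len(nrow(skeleton))) {
    ctr <- c(skeleton$z[i], skeleton$y[i], skeleton$x[i])
    amp <- exp(-skeleton$arclength_um[i] / spec$reach_um)
    zi <- max(1, ctr[1] - half[1]):min(spec$shape[1], ctr[1] + half[1])
    yi <- max(1, ctr[2] - half[2]):min(spec$shape[2], ctr[2] + half[2])
    xi <- max(1, ctr[3] - half[3]):min(spec$shape[3], ctr[3] + half[3])
    dz2 <- ((zi - ctr[1]) * sp[1])^2
    dy2 <- ((yi - ctr[2]) * sp[2])^2
    dx2 <- ((xi - ctr[3]) * sp[3])^2
    g <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    f[zi, yi, xi] <- f[zi, yi, xi] + amp * exp(-g / (2 * w^2))
  }
  # local leakage blob at the injection site (sigma = 2 * deposit width),
  # truncated at 3 sigma like the tube deposits so the field's support is
  # exactly the dilated skeleton plus the injection neighborhood
  leak_spec <- spec
  leak_spec$mode <- "diffusive"
  leak_spec$D <- (2 * w)^2 / 4
  leak_spec$t_min <- 1
  vox_vol <- prod(sp)
  leak <- simulate_diffusive_tracer(leak_spec)
  dz <- (seq_len(spec$shape[1]) - spec$injection[1]) * sp[1]
  dy <- (seq_len(spec$shape[2]) - spec$injection[2]) * sp[2]
  dx <- (seq_len(spec$shape[3]) - spec$injection[3]) * sp[3]
  r2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  leak[r2 > (6 * w)^2] <- 0
  f[!mask] <- 0
  f <- 0.9 * f / (sum(f) * vox_vol) + 0.1 * leak / (sum(leak) * vox_vol)
  f * (spec$mass / (sum(f) * vox_vol))
}

#' Simulate the tracer field a phantom specifies
#'
#' Dispatches on `spec$mode`.
#' @param spec a `phantom_spec`.
#' @return numeric array `(slices, rows, cols)`.
#' @export
simulate_tracer <- function(spec) {
  switch(spec$mode,
         diffusive = simulate_diffusive_tracer(spec),
         advective = simulate_advective_tracer(spec))
}
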