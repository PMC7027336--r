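#' Write a slice stack as numbered PNG files with a manifest
#'
#' One PNG per slice; channels are mapped to the PNG color planes named in
#' `channel_map` (default: tracer to green, nuclei to blue, matching the
#' FITC/DAPI export convention). A YAML manifest records file order,
#' spacings and the channel layout so the stack round-trips exactly.
#'
#' @param stack a [slice_stack()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param channel_map named character vector mapping channel names to
#'   `"red"`, `"green"`, `"blue"`.
#' @return the manifest path, invisibly.
#' @export
write_slice_stack <- function(stack, dir, prefix = "slice",
                              channel_map = c(tracer = "green",
                                              nuclei = "blue")) {
  stopifnot(inherits(stack, "slice_stack"))
  # keep the stack's own channel order in the manifest so reading it back
  # reproduces the original channel layout
  channel_map <- channel_map[intersect(stack$channels, names(channel_map))]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_slices(stack)
  d <- dim(stack$data)
  files <- character(n)
  plane_idx <- c(red = 1L, green = 2L, blue = 3L)
  for (i in seq_len(n)) {
    img <- array(0, c(d[2], d[3], 3))
    for (ch in names(channel_map))
      if (ch %in% stack$channels)
        img[, , plane_idx[[channel_map[[ch]]]]] <- stack$data[i, , , ch]
    files[i] <- sprintf("%s_%03d.png", prefix, i)
    png::writePNG(img, file.path(dir, files[i]))
  }
  manifest <- list(files = as.list(files),
                   in_plane_um = stack$in_plane_um,
                   axial_um = stack$axial_um,
                   channel_map = as.list(channel_map))
  path <- file.path(dir, paste0(prefix, "_manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a slice stack from a manifest
#' @param manifest_path path to a manifest written by [write_slice_stack()].
#' @return a [slice_stack()].
#' @export
read_slice_stack <- function(manifest_path) {
  m <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  channel_map <- unlist(m$channel_map)
  plane_idx <- c(red = 1L, green = 2L, blue = 3L)
  n <- length(m$files)
  first <- png::readPNG(file.path(dir, m$files[[1]]))
  dat <- array(0, c(n, dim(first)[1], dim(first)[2], length(channel_map)))
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, m$files[[i]]))
    for (j in seq_along(channel_map))
      dat[i, , , j] <- img[, , plane_idx[[channel_map[[j]]]]]
  }
  slice_stack(dat, names(channel_map), m$in_plane_um, m$axial_um)
}

#' Write / read per-slice rigid transforms as CSV
#'
#' Columns: `slice_index`, `angle_deg`, `dx_px`, `dy_px`.
#' @param transforms list of `rigid_transform2d`.
#' @param path CSV path.
#' @export
write_transforms_csv <- function(transforms, path) {
  write.csv(transforms_to_table(transforms), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transforms_csv
#' @export
read_transforms_csv <- function(path) {
  table_to_transforms(read.csv(path))
}

#' Write a 2-D projection (or any matrix on the 0-1 scale) as PNG
#' @param mat numeric matrix.
#' @param path output path.
#' @export
write_projection_png <- function(mat, path) {
  rng <- range(mat)
  if (diff(rng) > 0) mat <- (mat - rng[1]) / diff(rng)
  png::writePNG(mat, path)
  invisible(path)
}

#' Write phantom ground truth to disk
#'
#' The applied per-slice transforms go to CSV (`slice_index`, `angle_deg`,
#' `dx_px`, `dy_px`); the scalar truths (positive threshold and counts,
#' hemisphere counts, geometry) go to a JSON sidecar. Together these are
#' sufficient to test every downstream stage without the generating R
#' session.
#'
#' @param truth a `phantom_truth` (from [render_slices()]).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return (invisibly) the sidecar path.
#' @export
write_phantom_truth <- function(truth, dir, prefix = "truth") {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transforms_csv(truth$transforms,
                       file.path(dir, paste0(prefix, "_transforms.csv")))
  sidecar <- list(
    positive_threshold = truth$positive_threshold,
    positive_count = truth$positive_count,
    hemisphere_counts = as.list(truth$hemisphere_counts),
    shape = truth$spec$shape,
    spacing_um = phantom_spacing(truth$spec),
    injection = truth$spec$injection,
    mode = truth$spec$mode,
    seed = truth$spec$seed
  )
  path <- file.path(dir, paste0(prefix, "_scalars.json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hemisphere-separation polyline from CSV
#'
#' Expected columns: optional `slice_index`, then `vertex_row`, `vertex_col`
#' (vertices ordered along the polyline).
#' @param path CSV path.
#' @return a tibble.
#' @export
read_separation_csv <- function(path) {
  as_tibble(read.csv(path))
}
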