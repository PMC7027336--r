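#' In-plane rigid transforms
#'
#' A rigid transform acts on 2-D pixel coordinates `p = (x, y)` (x = 0-based
#' column, y = 0-based row) as `T(p) = R(theta) (p - c) + c + (dx, dy)`, where
#' `c` is the geometric image center and `R(theta)` rotates by `angle_deg`
#' degrees counter-clockwise in display coordinates (x right, y down).
#' Rotation about the image center matches how slices are mounted and
#' re-aligned; the convention is stated here because serial-section tooling
#' rarely agrees on one.
#'
#' @param angle_deg rotation in degrees about the image center.
#' @param dx,dy translation in pixels (columns, rows), applied after rotation.
#' @return an object of class `rigid_transform2d`.
#' @examples
#' tf <- rigid_transform(2, dx = 3, dy = -1)
#' compose_transform(tf, invert_transform(tf)) # ~ identity
#' @export
rigid_transform <- function(angle_deg = 0, dx = 0, dy = 0) {
  stopifnot(is.numeric(angle_deg), is.numeric(dx), is.numeric(dy))
  structure(list(angle_deg = as.numeric(angle_deg),
                 dx = as.numeric(dx), dy = as.numeric(dy)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> angle = %.4f deg, dx = %.4f px, dy = %.4f px\n",
              x$angle_deg, x$dx, x$dy))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`(a o b)(p) = a(b(p))`). With rotation about a shared image center the
#' composition is again center-anchored: angles add and `a`'s rotation acts
#' on `b`'s translation.
#'
#' @param a,b `rigid_transform2d` objects.
#' @return a `rigid_transform2d`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform2d"), inherits(b, "rigid_transform2d"))
  th <- a$angle_deg * pi / 180
  rigid_transform(
    angle_deg = a$angle_deg + b$angle_deg,
    dx = cos(th) * b$dx - sin(th) * b$dy + a$dx,
    dy = sin(th) * b$dx + cos(th) * b$dy + a$dy
  )
}

#' Invert a rigid transform
#' @param tf a `rigid_transform2d`.
#' @return the inverse `rigid_transform2d`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform2d"))
  th <- -tf$angle_deg * pi / 180
  rigid_transform(
    angle_deg = -tf$angle_deg,
    dx = -(cos(th) * tf$dx - sin(th) * tf$dy),
    dy = -(sin(th) * tf$dx + cos(th) * tf$dy)
  )
}

#' Apply a rigid transform to a 2-D image
#'
#' Resamples the image so that its content is moved by the forward transform;
#' the value at output pixel `q` is the bilinear sample of the input at
#' `T^{-1}(q)`. Pixels mapping outside the source are set to `fill`.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param tf a `rigid_transform2d`.
#' @param fill value for out-of-bounds samples (default 0; `NA` marks them).
#' @return a numeric matrix of the same shape.
#' @export
apply_transform <- function(img, tf, fill = 0) {
  stopifnot(is.matrix(img), inherits(tf, "rigid_transform2d"))
  .warp_rigid_cpp(img, tf$angle_deg, tf$dx, tf$dy, fill)
}

is_identity_transform <- function(tf, tol = 1e-8) {
  abs(tf$angle_deg) < tol && abs(tf$dx) < tol && abs(tf$dy) < tol
}

#' Tabulate a list of rigid transforms
#'
#' @param transforms list of `rigid_transform2d`, one per slice.
#' @return a tibble with columns `slice_index` (1-based), `angle_deg`,
#'   `dx_px`, `dy_px`.
#' @export
transforms_to_table <- function(transforms) {
  stopifnot(all(vapply(transforms, inherits, TRUE, "rigid_transform2d")))
  tibble(
    slice_index = seq_along(transforms),
    angle_deg = vapply(transforms, `[[`, 0, "angle_deg"),
    dx_px = vapply(transforms, `[[`, 0, "dx"),
    dy_px = vapply(transforms, `[[`, 0, "dy")
  )
}

#' @rdname transforms_to_table
#' @param table a data frame with the columns written by
#'   [transforms_to_table()].
#' @export
table_to_transforms <- function(table) {
  stopifnot(all(c("slice_index", "angle_deg", "dx_px", "dy_px") %in% names(table)))
  table <- table[order(table$slice_index), ]
  lapply(seq_len(nrow(table)), function(i)
    rigid_transform(table$angle_deg[i], table$dx_px[i], table$dy_px[i]))
}
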