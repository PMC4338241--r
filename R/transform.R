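#' Rigid transforms
#'
#' A rigid transform is a proper rotation `R` (3x3, orthonormal,
#' `det(R) = +1`) plus a translation `t` (mm). It acts on points as
#' `p' = R p + t`. Rigid transforms are the output currency of every
#' registration routine and of the phantom ground truth.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(1, 2, 3))
#' p <- c(10, 0, 0)
#' transform_points(invert_transform(tr), transform_points(tr, p))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix must have determinant +1 (no reflections)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points Numeric matrix with 3 columns (or a length-3 vector),
#'   one point per row, in mm.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  out <- pts %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, `+`)
  dimnames(out) <- dimnames(pts)
  if (vec) drop(out) else out
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first and
#' then `a` (i.e. `x -> a(b(x))`).
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Rotation helpers
#'
#' `rotation_about_axis()` builds a rotation matrix from an axis and an angle
#' in degrees (Rodrigues formula). `rotation_angle_deg()` extracts the
#' rotation angle of a rotation matrix; `transform_angle_deg()` and
#' `transform_translation_norm()` summarise the magnitude of a rigid
#' transform (used as rotation/translation error measures).
#'
#' @param axis Length-3 axis (not necessarily unit).
#' @param angle_deg Rotation angle in degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotation_about_axis
#' @param rotation 3x3 rotation matrix.
#' @export
rotation_angle_deg <- function(rotation) {
  c_th <- (sum(diag(rotation)) - 1) / 2
  acos(max(-1, min(1, c_th))) * 180 / pi
}

#' @rdname rotation_about_axis
#' @param transform A [rigid_transform()].
#' @export
transform_angle_deg <- function(transform) rotation_angle_deg(transform$rotation)

#' @rdname rotation_about_axis
#' @export
transform_translation_norm <- function(transform) sqrt(sum(transform$translation^2))

#' Rotation about an axis through a fixed point
#'
#' Returns the rigid transform that rotates by `angle_deg` about `axis`
#' passing through `center` (so `center` is a fixed point).
#'
#' @inheritParams rotation_about_axis
#' @param center Length-3 point the axis passes through (mm).
#' @export
rotation_about_point <- function(axis, angle_deg, center) {
  R <- rotation_about_axis(axis, angle_deg)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Sample a random rigid transform within bounds
#'
#' Rotation axis uniform on the sphere, rotation angle uniform on
#' `[0, max_rotation_deg]`, translation direction uniform with magnitude
#' uniform on `[0, max_translation_mm]`. The rotation is taken about
#' `center`, which keeps a compact object roughly in place.
#'
#' @param max_rotation_deg,max_translation_mm Nonnegative bounds.
#' @param center Fixed point of the rotation component (mm).
#' @return A [rigid_transform()]; draws from the current RNG stream.
#' @export
random_rigid_transform <- function(max_rotation_deg, max_translation_mm,
                                   center = c(0, 0, 0)) {
  stopifnot(max_rotation_deg >= 0, max_translation_mm >= 0)
  axis <- rnorm(3)
  if (sum(axis^2) < 1e-12) axis <- c(0, 0, 1)
  ang <- runif(1, 0, max_rotation_deg)
  tdir <- rnorm(3)
  if (sum(tdir^2) < 1e-12) tdir <- c(1, 0, 0)
  tdir <- tdir / sqrt(sum(tdir^2))
  tmag <- runif(1, 0, max_translation_mm)
  base <- rotation_about_point(axis, ang, center)
  rigid_transform(base$rotation, base$translation + tmag * tdir)
}
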