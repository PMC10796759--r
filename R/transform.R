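#' Rigid transform (rotation + translation)
#'
#' Rotations are given as three angles in degrees about the x, y and z world
#' axes, applied in that order (x, then y, then z) about a rotation center that
#' is supplied when the transform is applied (by convention the volume center).
#' Translation is in mm. A point transforms as
#' `y = R (x - c) + c + t` with `R = Rz %*% Ry %*% Rx`.
#'
#' @param rotation Numeric length-3, angles in degrees about x, y, z.
#' @param translation Numeric length-3, mm.
#' @return An object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(rotation = c(3, 1, -2), translation = c(2.5, -1, 0.6))
#' compose_transforms(tf, invert_transform(tf))  # ~ identity
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  if (length(rotation) != 3L || any(!is.finite(rotation)))
    rlang::abort("`rotation` must be 3 finite angles (degrees)")
  if (length(translation) != 3L || any(!is.finite(translation)))
    rlang::abort("`translation` must be 3 finite offsets (mm)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%s) deg, trans (%s) mm\n",
              paste(signif(x$rotation, 5), collapse = ", "),
              paste(signif(x$translation, 5), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return 3 x 3 rotation matrix `Rz Ry Rx`.
#' @export
rotation_matrix <- function(transform) {
  a <- transform$rotation * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Recover (rx, ry, rz) in degrees from R = Rz Ry Rx.
angles_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-12) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first and then `a`
#' (both about the same rotation center).
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  Ra <- rotation_matrix(a); Rb <- rotation_matrix(b)
  R <- Ra %*% Rb
  # y = Ra (Rb (x - c) + t_b) + c + t_a  =>  t = Ra t_b + t_a
  t <- as.vector(Ra %*% b$translation) + a$translation
  rigid_transform(angles_from_matrix(R), t)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()]; composing the two yields identity.
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform)
  rigid_transform(angles_from_matrix(t(R)),
                  as.vector(-t(R) %*% transform$translation))
}

#' Apply a rigid transform to world points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 matrix of world mm positions (or length-3 vector).
#' @param center Rotation center (mm).
#' @return Transformed points, n x 3 matrix.
#' @export
apply_transform <- function(transform, points, center = c(0, 0, 0)) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  R <- rotation_matrix(transform)
  sw <- sweep(as.matrix(points), 2, center)
  out <- sw %*% t(R)
  sweep(out, 2, center + transform$translation, `+`)
}

#' Discrepancy between two rigid transforms
#'
#' Measures how far `a` is from `b` as the geodesic rotation angle (degrees)
#' and the translation magnitude (mm) of the composition `a o b^-1`, which is
#' identity when the transforms agree.
#'
#' @param a,b [rigid_transform()] objects.
#' @return Named list with `rotation_deg` and `translation_mm`.
#' @export
transform_error <- function(a, b) {
  e <- compose_transforms(a, invert_transform(b))
  R <- rotation_matrix(e)
  cosang <- (sum(diag(R)) - 1) / 2
  list(rotation_deg = acos(max(-1, min(1, cosang))) * 180 / pi,
       translation_mm = sqrt(sum(e$translation^2)))
}

is_identity_transform <- function(transform, tol = 0) {
  all(abs(transform$rotation) <= tol) && all(abs(transform$translation) <= tol)
}
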