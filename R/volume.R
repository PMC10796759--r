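#' CT volume container
#'
#' A CT volume is a 3D array of Hounsfield units (HU) on an axis-aligned grid
#' with anisotropic voxel spacing. World coordinates are in millimetres; the
#' value of voxel `(i, j, k)` (1-based) sits at the voxel center
#' `origin + (c(i, j, k) - 1) * spacing`. Continuous positions are interpolated
#' trilinearly.
#'
#' @param data Numeric 3D array of intensities (HU; may be fractional after
#'   resampling).
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, world position (mm) of the center of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.6))
#' dim(vol$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L)
    rlang::abort("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    rlang::abort("all three volume dimensions must be >= 2")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    rlang::abort("`spacing` must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    rlang::abort("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    rlang::abort("volume intensities must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' World-coordinate helpers
#'
#' `volume_center()` returns the world position (mm) of the geometric center of
#' the grid; `volume_extent()` returns the world bounds spanned by voxel
#' centers, a 2 x 3 matrix of (min, max) per axis.
#'
#' @param volume A [ct_volume()].
#' @return Numeric length-3 (center) or a 2 x 3 matrix (extent).
#' @export
volume_center <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  volume$origin + (dim(volume$data) - 1) / 2 * volume$spacing
}

#' @rdname volume_center
#' @export
volume_extent <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  hi <- volume$origin + (dim(volume$data) - 1) * volume$spacing
  rbind(min = volume$origin, max = hi)
}

#' Sample a volume at arbitrary world positions
#'
#' Trilinear interpolation at world coordinates. Positions outside the grid of
#' voxel centers return `fill`.
#'
#' @param volume A [ct_volume()].
#' @param points Numeric matrix (n x 3) of world positions in mm, or a length-3
#'   vector for a single point.
#' @param fill Value returned outside the volume (default -1000 HU, air).
#' @return Numeric vector of length `nrow(points)`.
#' @export
sample_volume <- function(volume, points, fill = -1000) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  cpp_sample_points(as.vector(volume$data), dim(volume$data), volume$spacing,
                    volume$origin, points, fill)
}

#' Test whether world points are interpolable inside a volume
#'
#' @param volume A [ct_volume()].
#' @param points n x 3 matrix of world mm positions.
#' @return Logical vector.
#' @keywords internal
points_inside <- function(volume, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  ext <- volume_extent(volume)
  ok <- rep(TRUE, nrow(points))
  for (a in 1:3)
    ok <- ok & points[, a] >= ext[1, a] - 1e-9 & points[, a] <= ext[2, a] + 1e-9
  ok
}

#' Grid coordinates of every voxel center
#'
#' @param volume A [ct_volume()].
#' @param axis Axis index 1..3.
#' @return Numeric vector of world coordinates (mm) of voxel centers along
#'   `axis`.
#' @keywords internal
axis_coords <- function(volume, axis) {
  volume$origin[axis] + (seq_len(dim(volume$data)[axis]) - 1) *
    volume$spacing[axis]
}

# Check that two volumes live on the identical grid.
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
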