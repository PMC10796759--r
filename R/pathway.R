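#' Drill path (oriented canal segment)
#'
#' An oriented segment in world mm with a radius: the cylindrical model of the
#' drilled canal. The default radius is 1.525 mm, half the 3.05 mm outer
#' diameter of an 11G drilling tool.
#'
#' @param start,end World positions (mm) of the entry-side and distal
#'   endpoints.
#' @param radius Canal radius (mm).
#' @return An object of class `drill_path`.
#' @export
drill_path <- function(start, end, radius = 3.05 / 2) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3L || length(end) != 3L ||
      any(!is.finite(c(start, end))))
    rlang::abort("`start` and `end` must be finite length-3 mm positions")
  if (radius <= 0) rlang::abort("`radius` must be > 0")
  if (sqrt(sum((end - start)^2)) <= 0)
    rlang::abort("path length must be > 0")
  structure(list(start = start, end = end, radius = radius),
            class = "drill_path")
}

#' @export
print.drill_path <- function(x, ...) {
  cat(sprintf("<drill_path> length %.2f mm, radius %.3f mm, start (%s), end (%s)\n",
              path_length(x), x$radius,
              paste(sprintf("%.2f", x$start), collapse = ", "),
              paste(sprintf("%.2f", x$end), collapse = ", ")))
  invisible(x)
}

#' Path geometry helpers
#'
#' `path_length()` is the Euclidean start-end distance (mm);
#' `path_direction()` the unit vector from start to end; `reverse_path()` swaps
#' the endpoints; `extend_path()` moves the start backwards along the axis by
#' `pad_start` mm (e.g. into air, so an intensity profile has a pre-contact
#' baseline).
#'
#' @param path A [drill_path()].
#' @param pad_start Extension of the start, mm (>= 0).
#' @return Scalar, length-3 vector, or a new [drill_path()].
#' @export
path_length <- function(path) sqrt(sum((path$end - path$start)^2))

#' @rdname path_length
#' @export
path_direction <- function(path) (path$end - path$start) / path_length(path)

#' @rdname path_length
#' @export
reverse_path <- function(path) drill_path(path$end, path$start, path$radius)

#' @rdname path_length
#' @export
extend_path <- function(path, pad_start = 3) {
  stopifnot(pad_start >= 0)
  drill_path(path$start - pad_start * path_direction(path), path$end,
             path$radius)
}

#' Difference volume (bone removed by drilling)
#'
#' Voxelwise `pre - post_registered`; positive where bone was replaced by the
#' air-filled canal. Both volumes must share the grid.
#'
#' @param pre,post_registered [ct_volume()] objects on the same grid.
#' @return A [ct_volume()] of HU differences.
#' @export
difference_volume <- function(pre, post_registered) {
  stopifnot(inherits(pre, "ct_volume"),
            inherits(post_registered, "ct_volume"))
  if (!same_grid(pre, post_registered))
    rlang::abort("pre and post volumes are not on the same grid")
  ct_volume(pre$data - post_registered$data, spacing = pre$spacing,
            origin = pre$origin)
}

#' Segment the canal from a difference volume
#'
#' Thresholds the difference image and keeps the largest 26-connected
#' component, rejecting disconnected segmentation artifacts. Voxels are
#' returned with their world coordinates and weights equal to the difference
#' value, ready for weighted PCA.
#'
#' @param diff Difference [ct_volume()] from [difference_volume()].
#' @param threshold_hu Difference threshold in HU (> 0; default 400 — above
#'   trabecular partial-volume noise, below the bone-to-air contrast of the
#'   canal core).
#' @return Tibble with columns `x`, `y`, `z` (world mm) and `weight`;
#'   attributes `volume_extent` and `n_components`.
#' @export
segment_canal <- function(diff, threshold_hu = 400) {
  stopifnot(inherits(diff, "ct_volume"))
  if (threshold_hu <= 0) rlang::abort("`threshold_hu` must be > 0")
  idx <- which(diff$data >= threshold_hu)
  if (length(idx) < 20L)
    rlang::abort("canal not detected: fewer than 20 voxels above threshold")
  labels <- cpp_components26(dim(diff$data), as.numeric(idx - 1))
  keep <- labels == which.max(tabulate(labels))
  idx <- idx[keep]
  if (length(idx) < 20L)
    rlang::abort("canal not detected: largest component has fewer than 20 voxels")
  ijk <- arrayInd(idx, dim(diff$data)) - 1L
  pts <- sweep(sweep(ijk, 2, diff$spacing, `*`), 2, diff$origin, `+`)
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        weight = as.vector(diff$data)[idx])
  attr(out, "volume_extent") <- volume_extent(diff)
  attr(out, "n_components") <- max(labels)
  out
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Estimate the canal axis by weighted PCA
#'
#' The axis is the first eigenvector of the weighted covariance of the
#' segmented voxel coordinates (weights = difference magnitude, which
#' suppresses low-contrast rim artifacts); the centroid anchors it.
#' Provisional endpoints are the q and 1-q weighted quantiles (q = 0.5%) of
#' the projections onto the axis, oriented so that `start` is the endpoint
#' nearer the volume boundary (the entry side).
#'
#' @param voxels Weighted voxel tibble from [segment_canal()].
#' @param radius Canal radius for the returned path (mm).
#' @param q Endpoint quantile (default 0.005).
#' @param min_eigenratio Minimum first-to-second eigenvalue ratio; below it the
#'   blob has no dominant axis and an error is raised.
#' @return A [drill_path()].
#' @export
estimate_axis_pca <- function(voxels, radius = 3.05 / 2, q = 0.005,
                              min_eigenratio = 4) {
  if (nrow(voxels) < 20L)
    rlang::abort("need at least 20 weighted voxels to estimate an axis")
  pts <- as.matrix(voxels[, c("x", "y", "z")])
  w <- voxels$weight
  if (any(w < 0)) rlang::abort("voxel weights must be non-negative")
  w <- w / sum(w)
  ctr <- colSums(pts * w)
  cen <- sweep(pts, 2, ctr)
  cov_w <- crossprod(cen * sqrt(w))
  eig <- eigen(cov_w, symmetric = TRUE)
  if (eig$values[1] / max(eig$values[2], .Machine$double.eps) < min_eigenratio)
    rlang::abort("no dominant axis: first-to-second eigenvalue ratio below 4")
  axis <- eig$vectors[, 1]
  proj <- as.vector(cen %*% axis)
  qs <- weighted_quantile(proj, voxels$weight, c(q, 1 - q))
  p1 <- ctr + qs[1] * axis
  p2 <- ctr + qs[2] * axis
  ext <- attr(voxels, "volume_extent")
  if (!is.null(ext)) {
    bdist <- function(p) min(p - ext[1, ], ext[2, ] - p)
    if (bdist(p2) < bdist(p1)) { tmp <- p1; p1 <- p2; p2 <- tmp }
  }
  drill_path(p1, p2, radius)
}

# Disk-mean of a volume on the plane perpendicular to the path axis at a set
# of axial offsets (mm, measured from `path$start`). Shared by endpoint
# refinement and profile extraction.
disk_stencil <- function(path, disk_points) {
  if (disk_points != 1 && disk_points %% 2 == 0)
    rlang::abort("`disk_points` must be 1 or odd (center + two equal rings)")
  u <- path_direction(path)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  offsets <- matrix(0, nrow = 1, ncol = 3)
  if (disk_points > 1) {
    k <- (disk_points - 1) / 2
    ring <- function(r, phase) {
      ang <- phase + 2 * pi * (0:(k - 1)) / k
      outer(r * cos(ang), e1) + outer(r * sin(ang), e2)
    }
    offsets <- rbind(offsets, ring(path$radius / 2, pi / k),
                     ring(path$radius, 0))
  }
  offsets
}

disk_means <- function(volume, path, s_positions, disk_points = 13,
                       fill = 0) {
  u <- path_direction(path)
  offsets <- disk_stencil(path, disk_points)
  centers <- outer(s_positions, u)
  centers <- sweep(centers, 2, path$start, `+`)
  np <- nrow(offsets)
  pts <- centers[rep(seq_along(s_positions), each = np), , drop = FALSE] +
    offsets[rep(seq_len(np), times = length(s_positions)), , drop = FALSE]
  vals <- sample_volume(volume, pts, fill = fill)
  m <- matrix(vals, nrow = np)
  colMeans(m)
}

#' Refine canal endpoints to sub-voxel precision
#'
#' Walks each provisional endpoint along the axis in `step` mm increments
#' (from the canal interior outwards) and places the endpoint where the
#' disk-mean of the difference image first falls below 50% of the canal's
#' median difference (half-maximum edge rule), with linear interpolation of
#' the crossing. The search is capped at +/- `cap` mm around the provisional
#' endpoint; if no crossing is found the provisional endpoint is kept and a
#' warning is emitted. This is a programmatic stand-in for interactive
#' fine-tuning.
#'
#' @param diff Difference [ct_volume()].
#' @param path Provisional [drill_path()] from [estimate_axis_pca()].
#' @param step Walk step (mm, default 0.05).
#' @param cap Search range around each provisional endpoint (mm, default 2).
#' @param disk_points Stencil size for the disk-mean (see [extract_profile()]).
#' @return The refined [drill_path()].
#' @export
refine_endpoints <- function(diff, path, step = 0.05, cap = 2,
                             disk_points = 13) {
  L <- path_length(path)
  u <- path_direction(path)
  interior <- seq(0.15 * L, 0.85 * L, by = max(step, L / 200))
  med <- stats::median(disk_means(diff, path, interior, disk_points))
  half <- 0.5 * med

  edge_scan <- function(t_inner, t_outer) {
    ts <- seq(t_inner, t_outer, by = if (t_outer > t_inner) step else -step)
    f <- disk_means(diff, path, ts, disk_points)
    below <- which(f < half)
    if (length(below) == 0 || below[1] == 1) return(NULL)
    i <- below[1]
    # linear interpolation of the half-maximum crossing
    ts[i - 1] + (half - f[i - 1]) / (f[i] - f[i - 1]) * (ts[i] - ts[i - 1])
  }

  t_start <- edge_scan(cap, -cap)
  if (is.null(t_start)) {
    rlang::warn("no half-maximum crossing within cap at start; keeping provisional endpoint")
    t_start <- 0
  }
  t_end <- edge_scan(L - cap, L + cap)
  if (is.null(t_end)) {
    rlang::warn("no half-maximum crossing within cap at end; keeping provisional endpoint")
    t_end <- L
  }
  drill_path(path$start + t_start * u, path$start + t_end * u, path$radius)
}

#' Cylindrical canal mask
#'
#' Marks every voxel whose center lies within `path$radius` of the axis with
#' an axial projection in `[0, length]`.
#'
#' @param grid_of [ct_volume()] supplying the grid.
#' @param path A [drill_path()].
#' @return A [ct_volume()] with 0/1 data.
#' @export
cylinder_mask <- function(grid_of, path) {
  stopifnot(inherits(grid_of, "ct_volume"), inherits(path, "drill_path"))
  d <- dim(grid_of$data)
  u <- path_direction(path)
  L <- path_length(path)
  lo <- pmin(path$start, path$end) - path$radius - grid_of$spacing
  hi <- pmax(path$start, path$end) + path$radius + grid_of$spacing
  i0 <- pmax(1L, floor((lo - grid_of$origin) / grid_of$spacing) + 1L)
  i1 <- pmin(d, ceiling((hi - grid_of$origin) / grid_of$spacing) + 1L)
  if (any(i1 < i0)) rlang::abort("empty mask: path does not intersect volume")
  xs <- grid_of$origin[1] + (i0[1]:i1[1] - 1) * grid_of$spacing[1]
  ys <- grid_of$origin[2] + (i0[2]:i1[2] - 1) * grid_of$spacing[2]
  zs <- grid_of$origin[3] + (i0[3]:i1[3] - 1) * grid_of$spacing[3]
  nb <- c(length(xs), length(ys), length(zs))
  px <- rep(xs, times = nb[2] * nb[3]) - path$start[1]
  py <- rep(rep(ys, each = nb[1]), times = nb[3]) - path$start[2]
  pz <- rep(zs, each = nb[1] * nb[2]) - path$start[3]
  tax <- px * u[1] + py * u[2] + pz * u[3]
  rad2 <- pmax(0, px^2 + py^2 + pz^2 - tax^2)
  inside <- tax >= 0 & tax <= L & rad2 <= path$radius^2 + 1e-12
  if (!any(inside)) rlang::abort("empty mask: no voxel centers inside cylinder")
  mask <- array(0, d)
  block <- array(as.numeric(inside), nb)
  mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- block
  ct_volume(mask, spacing = grid_of$spacing, origin = grid_of$origin)
}

#' Extract the density profile along a drill path
#'
#' Samples the pre-interventional volume along the canal axis at uniform
#' arc-length steps. At each position a fixed stencil on the perpendicular
#' plane (axis point plus two concentric rings of `(disk_points - 1) / 2`
#' points at radius/2 and radius) is sampled trilinearly; per-step mean, min
#' and max over the stencil form the profile channels. The number of steps is
#' `floor(L / ds) + 1`.
#'
#' @param volume Pre-interventional [ct_volume()].
#' @param path A [drill_path()] (possibly extended into air, see
#'   [extend_path()]).
#' @param ds Arc step in mm (default 0.1).
#' @param disk_points Stencil size (default 13 = center + 2 rings of 6); 1
#'   samples the axis only.
#' @param meta Optional [specimen_meta()] attached to the profile.
#' @return A `density_profile`: tibble with columns `s_mm`, `hu_mean`,
#'   `hu_min`, `hu_max`; attributes `path`, `ds`, `disk_points`, `meta`.
#' @export
extract_profile <- function(volume, path, ds = 0.1, disk_points = 13,
                            meta = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(path, "drill_path"))
  L <- path_length(path)
  n <- floor(L / ds + 1e-9) + 1
  s <- (seq_len(n) - 1) * ds
  u <- path_direction(path)
  offsets <- disk_stencil(path, disk_points)
  np <- nrow(offsets)
  centers <- sweep(outer(s, u), 2, path$start, `+`)
  pts <- centers[rep(seq_len(n), each = np), , drop = FALSE] +
    offsets[rep(seq_len(np), times = n), , drop = FALSE]
  ok <- points_inside(volume, pts)
  if (!all(ok)) {
    bad_s <- s[ceiling(which(!ok)[1] / np)]
    rlang::abort(sprintf("stencil point outside volume at s = %.2f mm", bad_s))
  }
  vals <- matrix(sample_volume(volume, pts), nrow = np)
  out <- tibble::tibble(s_mm = s,
                        hu_mean = colMeans(vals),
                        hu_min = apply(vals, 2, min),
                        hu_max = apply(vals, 2, max))
  attr(out, "path") <- path
  attr(out, "ds") <- ds
  attr(out, "disk_points") <- disk_points
  attr(out, "meta") <- meta
  class(out) <- c("density_profile", class(out))
  out
}
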