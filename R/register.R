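#' Resample a volume under a rigid transform
#'
#' Pull-back resampling onto the input grid: the output voxel at world position
#' `x` takes the trilinearly interpolated value of `volume` at `T(x)`, where
#' `T` rotates about the volume center. Positions mapped outside the volume are
#' filled with `fill` (air). Spacing and origin are unchanged. An identity
#' transform returns the input unchanged.
#'
#' @param volume A [ct_volume()].
#' @param transform A [rigid_transform()].
#' @param fill Out-of-field value (default -1000 HU).
#' @return A [ct_volume()] on the same grid.
#' @export
resample_volume <- function(volume, transform, fill = -1000) {
  stopifnot(inherits(volume, "ct_volume"), inherits(transform,
                                                    "rigid_transform"))
  if (is_identity_transform(transform)) return(volume)
  d <- dim(volume$data)
  out <- cpp_resample_rigid(as.vector(volume$data), d, volume$spacing,
                            volume$origin, rotation_matrix(transform),
                            transform$translation, volume_center(volume),
                            fill)
  ct_volume(array(out, d), spacing = volume$spacing, origin = volume$origin)
}

# Downsample a volume by a power-of-two factor with block means. Voxel centers
# stay aligned: the new origin sits at the mean of each 2^3 block's centers.
downsample_volume <- function(volume, factor) {
  stopifnot(factor %in% c(1, 2, 4))
  out <- volume
  while (factor > 1) {
    d <- dim(out$data)
    arr <- cpp_downsample2(as.vector(out$data), d)
    out <- ct_volume(array(arr, dim(arr)), spacing = out$spacing * 2,
                     origin = out$origin + out$spacing / 2)
    factor <- factor / 2
  }
  out
}

# Separable 1-2-1 binomial smoothing (replicated borders). Applied to both
# volumes before the metric so that the interpolation blur the resampled
# moving image carries is small relative to a blur both images share;
# otherwise the metric minimum is biased by the one-sided smoothing.
smooth_binomial <- function(volume) {
  a <- volume$data
  d <- dim(a)
  pad_ix <- function(n) c(1L, seq_len(n), n)
  for (ax in 1:3) {
    p <- switch(ax,
                a[pad_ix(d[1]), , , drop = FALSE],
                a[, pad_ix(d[2]), , drop = FALSE],
                a[, , pad_ix(d[3]), drop = FALSE])
    n <- d[ax]
    a <- switch(ax,
                0.25 * p[1:n, , , drop = FALSE] +
                  0.5 * p[2:(n + 1), , , drop = FALSE] +
                  0.25 * p[3:(n + 2), , , drop = FALSE],
                0.25 * p[, 1:n, , drop = FALSE] +
                  0.5 * p[, 2:(n + 1), , drop = FALSE] +
                  0.25 * p[, 3:(n + 2), , drop = FALSE],
                0.25 * p[, , 1:n, drop = FALSE] +
                  0.5 * p[, , 2:(n + 1), drop = FALSE] +
                  0.25 * p[, , 3:(n + 2), drop = FALSE])
  }
  ct_volume(a, spacing = volume$spacing, origin = volume$origin)
}

#' Rigid registration of a post volume onto a pre volume
#'
#' Recovers the rigid correction that brings `moving` into spatial concordance
#' with `fixed` by minimizing the mean squared HU difference over a body mask
#' (`fixed > mask_threshold`), using a three-level multi-resolution pyramid
#' (downsampling factors 4, 2, 1) with derivative-free Nelder-Mead search at
#' each level. Both volumes must share the grid; the pair is assumed
#' monomodal (same scanner and protocol), which is why a simple squared
#' difference metric suffices. `init` plays the role of a manual pre-alignment
#' and seeds the coarsest level.
#'
#' @param fixed,moving [ct_volume()] objects on the same grid.
#' @param init Optional initial [rigid_transform()].
#' @param mask_threshold HU threshold of the body mask (default -500).
#' @param max_points Cap on the number of mask voxels used per level (they are
#'   subsampled deterministically).
#' @param maxit Nelder-Mead iteration caps per pyramid level (coarse to fine).
#' @return The recovered [rigid_transform()]; `resample_volume(moving, t)`
#'   approximates `fixed`. Attributes: `metric` (masked MSD at the solution,
#'   full resolution), `metric_init`, `metric_by_level`, `convergence`.
#' @export
register_rigid <- function(fixed, moving, init = NULL, mask_threshold = -500,
                           max_points = 60000,
                           maxit = c(1200, 800, 500)) {
  stopifnot(inherits(fixed, "ct_volume"), inherits(moving, "ct_volume"))
  if (!identical(dim(fixed$data), dim(moving$data)) ||
      any(abs(fixed$spacing - moving$spacing) > 1e-9))
    rlang::abort("fixed and moving volumes must share grid shape and spacing")
  if (is.null(init)) init <- rigid_transform()
  center <- volume_center(fixed)

  level_data <- function(factor) {
    f <- smooth_binomial(downsample_volume(fixed, factor))
    m <- smooth_binomial(downsample_volume(moving, factor))
    idx <- which(f$data > mask_threshold)
    if (length(idx) == 0)
      rlang::abort("no voxels in body mask; check mask_threshold")
    if (length(idx) > max_points) {
      stride <- ceiling(length(idx) / max_points)
      idx <- idx[seq(1L, length(idx), by = stride)]
    }
    d <- dim(f$data)
    ijk <- arrayInd(idx, d) - 1L
    pts <- sweep(sweep(ijk, 2, f$spacing, `*`), 2, f$origin, `+`)
    storage.mode(pts) <- "double"
    list(vals = as.vector(f$data)[idx], pts = pts, moving = m)
  }

  objective <- function(par, lv) {
    tf <- rigid_transform(par[4:6], par[1:3])
    cpp_msd(lv$vals, lv$pts, as.vector(lv$moving$data), dim(lv$moving$data),
            lv$moving$spacing, lv$moving$origin, rotation_matrix(tf),
            tf$translation, center, -1000)
  }

  par <- c(init$translation, init$rotation)
  factors <- c(4, 2, 1)
  metric_by_level <- numeric(0)
  conv <- 0L
  lv_fine <- NULL
  for (li in seq_along(factors)) {
    lv <- level_data(factors[li])
    if (factors[li] == 1) lv_fine <- lv
    opt <- stats::optim(par, objective, lv = lv, method = "Nelder-Mead",
                        control = list(maxit = maxit[li], reltol = 1e-10))
    par <- opt$par
    conv <- max(conv, opt$convergence)
    metric_by_level <- c(metric_by_level, opt$value)
  }
  # restarted polishing passes at full resolution: re-initializing the simplex
  # lets Nelder-Mead escape premature shrinkage
  value <- metric_by_level[length(metric_by_level)]
  plateaued <- FALSE
  for (restart in 1:6) {
    opt <- stats::optim(par, objective, lv = lv_fine, method = "Nelder-Mead",
                        control = list(maxit = maxit[length(maxit)],
                                       reltol = 1e-12))
    improved <- value - opt$value
    par <- opt$par
    value <- opt$value
    if (improved <= 1e-8 * max(value, 1e-12)) { plateaued <- TRUE; break }
  }
  if (!plateaued && opt$convergence != 0L)
    rlang::warn("registration did not fully converge; returning best transform found")

  result <- rigid_transform(par[4:6], par[1:3])
  metric_init <- objective(c(init$translation, init$rotation), lv_fine)
  attr(result, "metric") <- opt$value
  attr(result, "metric_init") <- metric_init
  attr(result, "metric_by_level") <- metric_by_level
  attr(result, "convergence") <- max(conv, opt$convergence)
  result
}
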