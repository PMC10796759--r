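# Synthetic vertebra-like phantom: a cortical ellipsoidal shell around textured
# trabecular interior on an air background, with a known oblique drill canal,
# a known rigid pre/post misalignment, and force traces generated from the
# ground-truth density profile through a declared monotone link. Every random
# draw flows from one explicit seed; ground truth is recorded so each
# downstream stage can be scored.

# Run code with a local, restorable RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

smoothstep01 <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' Ground truth of a synthetic phantom
#'
#' Bundles everything needed to score the pipeline on synthetic data: the true
#' canal geometry, the rigid misalignment applied to the post volume, the
#' affine density-to-force link, noise settings, and the seed.
#'
#' @param path True canal as a [drill_path()].
#' @param misalignment [rigid_transform()] applied to the post volume.
#' @param link List with `intercept` (N) and `slope` (N per GV) of the affine
#'   density-to-force link.
#' @param noise List with `hu_sd` (HU), `force_sd` (N) and `ar1` (AR(1)
#'   coefficient, |ar1| < 1) for the force noise.
#' @param insertion_offset Air travel of the drill tip before bone contact
#'   (mm); makes force/intensity alignment nontrivial.
#' @param seed Integer seed all phantom randomness derives from.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(path, misalignment, link, noise, insertion_offset,
                          seed) {
  if (path$radius <= 0) rlang::abort("canal radius must be > 0")
  if (abs(noise$ar1) >= 1) rlang::abort("|ar1| must be < 1")
  structure(list(path = path, misalignment = misalignment, link = link,
                 noise = noise, insertion_offset = insertion_offset,
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n  canal: ")
  print(x$path)
  cat("  misalignment: ")
  print(x$misalignment)
  cat(sprintf("  link: F = %.4g + %.4g * GV (N);  noise: hu_sd %.3g, force_sd %.3g, ar1 %.3g\n",
              x$link$intercept, x$link$slope, x$noise$hu_sd, x$noise$force_sd,
              x$noise$ar1))
  cat(sprintf("  insertion offset %.3g mm, seed %d\n", x$insertion_offset,
              x$seed))
  invisible(x)
}

# Deterministic phantom anatomy relative to the grid extent: an ellipsoidal
# vertebral "body" plus two asymmetric lumps (a posterior-arch/spinous block
# and one lateral process). The asymmetry is what makes rigid rotations
# observable; a lone smooth ellipsoid is nearly rotation-invariant.
phantom_geometry <- function(extent) {
  center <- extent / 2
  list(center = center,
       semi = c(0.38, 0.33, 0.44) * extent,
       lumps = list(
         list(center = center + c(0.04, -0.32, 0.06) * extent,
              semi = c(0.10, 0.12, 0.09) * extent),
         list(center = center + c(0.34, -0.10, 0.14) * extent,
              semi = c(0.11, 0.08, 0.07) * extent)))
}

# Normalized ellipsoid radius of world points for given center/semi-axes.
ellipsoid_rho <- function(points, center, semi) {
  sqrt(((points[, 1] - center[1]) / semi[1])^2 +
       ((points[, 2] - center[2]) / semi[2])^2 +
       ((points[, 3] - center[3]) / semi[3])^2)
}

#' Generate a vertebra-like CT phantom with a known canal
#'
#' Builds a pre-interventional volume: an ellipsoidal body of textured
#' trabecular bone (smoothed Gaussian field) inside a cortical shell on an air
#' background, plus ground truth for an oblique drill canal crossing the shell
#' into the interior. Boundaries are softened over roughly one voxel to mimic
#' partial-volume averaging. Nothing is carved here; see [carve_canal()].
#'
#' @param shape Grid size, all dims >= 48 (default 128^3).
#' @param spacing Voxel size in mm, each within `[0.2, 1]` (default 0.5 mm).
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @param trabecular_mean,trabecular_sd Mean and sd (HU) of the interior
#'   texture.
#' @param cortical_hu Shell intensity (HU).
#' @param air_hu Background intensity (HU).
#' @param shell_thickness Cortical shell thickness (mm).
#' @param hu_noise_sd Additional white HU noise over the whole volume (sd, HU).
#' @param canal_radius Canal radius in mm (default 1.525, an 11G tool).
#' @param canal_length_range Range (mm) the bone-traversing canal length is
#'   drawn from; `NULL` (default) scales with the volume, 45-62% of the
#'   smallest extent (28.6-39.4 mm for the default 128^3 grid of 0.5 mm
#'   voxels, matching thoraco-lumbar pathway lengths).
#' @param misalignment [rigid_transform()] applied to the post volume, or
#'   `NULL` to draw one uniformly within `misalignment_max`.
#' @param misalignment_max Length-2: max |rotation| (deg) and |translation|
#'   (mm) for the random misalignment.
#' @param path Optionally a fixed [drill_path()] to use instead of a random
#'   one; an error is raised if it is not fully inside the volume.
#' @param link,noise,insertion_offset See [phantom_truth()].
#' @return List with `volume` (the pre [ct_volume()]) and `truth`
#'   ([phantom_truth()]).
#' @examples
#' ph <- make_phantom(shape = c(48, 48, 48), spacing = c(0.6, 0.6, 0.6),
#'                    seed = 1)
#' ph$truth
#' @export
make_phantom <- function(shape = c(128, 128, 128), spacing = c(0.5, 0.5, 0.5),
                         seed, trabecular_mean = 300, trabecular_sd = 60,
                         cortical_hu = 1200, air_hu = -1000,
                         shell_thickness = 1.5, hu_noise_sd = 0,
                         canal_radius = 3.05 / 2,
                         canal_length_range = NULL,
                         misalignment = NULL, misalignment_max = c(3, 2.5),
                         path = NULL,
                         link = list(intercept = 0.2, slope = 0.0025),
                         noise = list(hu_sd = hu_noise_sd, force_sd = 0.15,
                                      ar1 = 0.8),
                         insertion_offset = 1.3) {
  shape <- as.integer(shape)
  if (any(shape < 48L)) rlang::abort("phantom shape must be >= 48 per axis")
  if (any(spacing < 0.2 - 1e-12) || any(spacing > 1 + 1e-12))
    rlang::abort("phantom spacing must lie in [0.2, 1] mm")
  extent <- (shape - 1) * spacing
  if (is.null(canal_length_range))
    canal_length_range <- c(0.45, 0.62) * min(extent)
  geom <- phantom_geometry(extent)
  center <- geom$center
  semi <- geom$semi

  vol <- with_seed(seed, {
    # low-frequency trabecular texture: coarse white noise, trilinearly
    # upsampled (one knot every ~2 mm)
    step <- pmax(1L, as.integer(round(2 / spacing)))
    cdim <- pmax(2L, shape %/% step + 2L)
    coarse <- ct_volume(array(stats::rnorm(prod(cdim)), cdim),
                        spacing = spacing * step,
                        origin = c(0, 0, 0))
    xs <- (seq_len(shape[1]) - 1) * spacing[1]
    ys <- (seq_len(shape[2]) - 1) * spacing[2]
    zs <- (seq_len(shape[3]) - 1) * spacing[3]
    pts <- cbind(rep(xs, times = shape[2] * shape[3]),
                 rep(rep(ys, each = shape[1]), times = shape[3]),
                 rep(zs, each = shape[1] * shape[2]))
    field <- sample_volume(coarse, pts, fill = 0)
    field <- (field - mean(field)) / stats::sd(field) * trabecular_sd

    # body plus posterior-arch and lateral-process lumps: real vertebrae are
    # strongly asymmetric, which is what anchors rotational registration
    hu <- rep(air_hu, nrow(pts))
    for (g in c(list(list(center = center, semi = semi)), geom$lumps)) {
      rho <- ellipsoid_rho(pts, g$center, g$semi)
      # interface softening over ~2 voxels: CT is band-limited by the
      # scanner PSF, and edges sharper than the grid alias under resampling
      w_rho <- 2 * max(spacing) / mean(g$semi)
      t_outer <- smoothstep01((1 - rho) / w_rho + 0.5)
      delta <- shell_thickness / mean(g$semi)
      t_inner <- smoothstep01((1 - delta - rho) / w_rho + 0.5)
      hu_g <- air_hu + t_outer * (cortical_hu - air_hu) +
        t_inner * (trabecular_mean + field - cortical_hu)
      hu <- pmax(hu, hu_g)
    }
    if (hu_noise_sd > 0) hu <- hu + stats::rnorm(length(hu), 0, hu_noise_sd)
    ct_volume(array(hu, shape), spacing = spacing, origin = c(0, 0, 0))
  })

  if (is.null(path)) {
    path <- with_seed(seed + 7777L, {
      draw_canal_path(vol, geom, canal_radius, canal_length_range)
    })
  }
  check_canal_inside(vol, path)

  if (is.null(misalignment)) {
    misalignment <- with_seed(seed + 15551L, {
      rigid_transform(stats::runif(3, -misalignment_max[1],
                                   misalignment_max[1]),
                      stats::runif(3, -misalignment_max[2],
                                   misalignment_max[2]))
    })
  }
  noise$hu_sd <- if (is.null(noise$hu_sd)) hu_noise_sd else noise$hu_sd
  truth <- phantom_truth(path, misalignment, link, noise, insertion_offset,
                         seed)
  list(volume = vol, truth = truth)
}

# Rejection-sample an oblique canal: entry on the body's shell surface, end in
# the trabecular interior, the whole cylinder (plus an air approach segment)
# inside the volume, and the approach segment clear of the arch/process lumps
# so the pre-contact profile really is air.
draw_canal_path <- function(vol, geom, radius, length_range,
                            max_tries = 500L) {
  ext <- volume_extent(vol)
  center <- geom$center
  semi <- geom$semi
  margin <- radius + 2
  for (i in seq_len(max_tries)) {
    p <- center + stats::runif(3, -0.25, 0.25) * semi
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    if (any(abs(d) > 0.93) || any(abs(d) < 0.15)) next  # keep it oblique
    # ray p - t*d exits the ellipsoid at the positive root
    q <- d / semi
    pc <- (p - center) / semi
    a <- sum(q^2); b <- -2 * sum(pc * q); cc <- sum(pc^2) - 1
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) next
    t1 <- (-b + sqrt(disc)) / (2 * a)
    entry <- p - t1 * d
    len <- stats::runif(1, length_range[1], length_range[2])
    end <- entry + len * d
    if (ellipsoid_rho(matrix(end, ncol = 3), center, semi) > 0.88) next
    probe <- rbind(entry - 4 * d, entry, end)
    if (any(probe < rep(ext[1, ] + margin, each = 3)) ||
        any(probe > rep(ext[2, ] - margin, each = 3))) next
    pad <- outer(seq(0.5, 5, by = 0.5), -d)
    pad <- sweep(pad, 2, entry, `+`)
    clear <- TRUE
    for (g in geom$lumps)
      clear <- clear && all(ellipsoid_rho(pad, g$center, g$semi) > 1.15)
    if (!clear) next
    return(drill_path(entry, end, radius))
  }
  rlang::abort("could not place a canal inside the phantom volume")
}

check_canal_inside <- function(vol, path, pad = 0) {
  ext <- volume_extent(vol)
  pts <- rbind(path$start, path$end)
  m <- path$radius + pad
  if (any(pts < rep(ext[1, ] + m, each = 2)) ||
      any(pts > rep(ext[2, ] - m, each = 2)))
    rlang::abort("canal not fully inside volume")
  invisible(TRUE)
}

#' Carve the drill canal into a phantom and apply the misalignment
#'
#' Voxels inside a flat-ended cylinder around the true canal axis are set to
#' air (plus independent HU noise); the wall is softened over roughly one
#' voxel to mimic partial-volume averaging. The recorded rigid misalignment is
#' then applied by resampling, producing the post-interventional volume.
#'
#' @param pre Pre-interventional [ct_volume()] from [make_phantom()].
#' @param truth Matching [phantom_truth()].
#' @param air_hu Intensity the canal is filled with (default -1000 HU).
#' @return The post-interventional [ct_volume()].
#' @export
carve_canal <- function(pre, truth, air_hu = -1000) {
  stopifnot(inherits(pre, "ct_volume"), inherits(truth, "phantom_truth"))
  path <- truth$path
  check_canal_inside(pre, path)
  if (path$radius < min(pre$spacing[1:2]))
    rlang::warn("canal radius below one in-plane voxel; canal may vanish under partial-volume softening")
  d <- dim(pre$data)
  u <- (path$end - path$start) / path_length(path)
  L <- path_length(path)

  # bounding voxel box of the cylinder (+2 voxels)
  lo <- pmin(path$start, path$end) - path$radius - 2 * pre$spacing
  hi <- pmax(path$start, path$end) + path$radius + 2 * pre$spacing
  i0 <- pmax(1L, floor((lo - pre$origin) / pre$spacing) + 1L)
  i1 <- pmin(d, ceiling((hi - pre$origin) / pre$spacing) + 1L)
  xs <- pre$origin[1] + (i0[1]:i1[1] - 1) * pre$spacing[1]
  ys <- pre$origin[2] + (i0[2]:i1[2] - 1) * pre$spacing[2]
  zs <- pre$origin[3] + (i0[3]:i1[3] - 1) * pre$spacing[3]
  nb <- c(length(xs), length(ys), length(zs))
  px <- rep(xs, times = nb[2] * nb[3]) - path$start[1]
  py <- rep(rep(ys, each = nb[1]), times = nb[3]) - path$start[2]
  pz <- rep(zs, each = nb[1] * nb[2]) - path$start[3]
  tax <- px * u[1] + py * u[2] + pz * u[3]
  rad2 <- pmax(0, px^2 + py^2 + pz^2 - tax^2)
  # signed distance outside a flat-ended cylinder
  d_out <- pmax(sqrt(rad2) - path$radius, -tax, tax - L)
  pv <- max(pre$spacing)
  w <- smoothstep01(0.5 - d_out / pv)

  carved <- pre
  sel <- w > 0
  if (any(sel)) {
    block <- carved$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    canal_val <- rep(air_hu, sum(sel))
    if (truth$noise$hu_sd > 0)
      canal_val <- with_seed(truth$seed + 33311L,
                             canal_val + stats::rnorm(length(canal_val), 0,
                                                      truth$noise$hu_sd))
    block[sel] <- (1 - w[sel]) * block[sel] + w[sel] * canal_val
    carved$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- block
  }
  if (is_identity_transform(truth$misalignment)) carved
  else resample_volume(carved, truth$misalignment)
}

#' Simulate a drilling force trace from a density profile
#'
#' The force model is declared, not biomechanical: after an air approach of
#' `truth$insertion_offset` mm the clean force is affine in the gray value
#' sampled at the tip position, `F(x) = a + b * (GV(x - s0) - GV(0))`, and
#' stationary AR(1) Gaussian noise is added. Sampling follows the measurement
#' setup: constant feed (2 mm/s) at 1 kHz.
#'
#' @param profile A [density_profile][extract_profile()] covering the canal
#'   (typically extracted along the true path extended into air, see
#'   [extend_path()]). Uses the `gv_mean` channel, or converts `hu_mean` with
#'   default [hu_to_gv()] settings.
#' @param truth [phantom_truth()] carrying link, noise and insertion offset.
#' @param feed_velocity mm/s (default 2).
#' @param sample_rate Hz (default 1000).
#' @param target_rho Optional population Spearman correlation in (0, 1]; when
#'   given, the force noise sd is set from the Gaussian-copula relation
#'   `rho_pearson = 2 sin(pi rho_s / 6)` (exact for Gaussian density values,
#'   approximate otherwise) and `truth$noise$force_sd` is ignored.
#' @param seed Seed for the noise draw; defaults to one derived from
#'   `truth$seed`.
#' @return A [force_trace()] with attribute `insertion_offset`.
#' @export
simulate_force_trace <- function(profile, truth, feed_velocity = 2,
                                 sample_rate = 1000, target_rho = NULL,
                                 seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  gv <- if ("gv_mean" %in% names(profile)) profile$gv_mean
        else hu_to_gv(profile$hu_mean)
  s <- profile$s_mm
  if (truth$link$slope < 0)
    rlang::abort("link slope must be >= 0 (monotone link)")
  s0 <- truth$insertion_offset
  if (s0 <= 0) rlang::abort("insertion offset must be > 0")
  dx <- feed_velocity / sample_rate
  n <- floor((s0 + max(s)) / dx + 1e-9) + 1
  x <- (seq_len(n) - 1) * dx
  gv_at <- stats::approx(s, gv, xout = pmax(x - s0, 0), rule = 2)$y
  clean <- truth$link$intercept +
    truth$link$slope * (gv_at - gv[1]) * (x >= s0)

  sd_f <- truth$noise$force_sd
  if (!is.null(target_rho)) {
    if (target_rho <= 0 || target_rho > 1)
      rlang::abort("requested population Spearman rho must be in (0, 1]")
    rho_p <- 2 * sin(pi * target_rho / 6)
    in_bone <- s >= s0_profile_onset(s, gv)
    sd_sig <- truth$link$slope * stats::sd(gv[in_bone])
    sd_f <- if (target_rho == 1) 0 else sd_sig * sqrt(1 / rho_p^2 - 1)
  }
  eps <- 0
  if (sd_f > 0) {
    phi <- truth$noise$ar1
    eps <- with_seed(if (is.null(seed)) truth$seed + 44111L else seed, {
      innov <- stats::rnorm(n, 0, sd_f * sqrt(1 - phi^2))
      e0 <- stats::rnorm(1, 0, sd_f)
      as.numeric(stats::filter(innov, phi, method = "recursive",
                               init = e0))
    })
  }
  out <- force_trace((seq_len(n) - 1) / sample_rate, clean + eps,
                     sample_rate = sample_rate, feed_velocity = feed_velocity)
  attr(out, "insertion_offset") <- s0
  out
}

# First arc position where the profile has clearly left its air baseline; used
# only to pick the in-bone region for noise calibration.
s0_profile_onset <- function(s, gv) {
  base <- gv[1]
  thr <- base + 0.05 * (max(gv) - base)
  idx <- which(gv > thr)
  if (length(idx) == 0) s[1] else s[idx[1]]
}

#' Write / read the phantom ground-truth sidecar
#'
#' The JSON sidecar records canal endpoints and radius, the misalignment, the
#' force link and noise parameters, the insertion offset and the seed —
#' sufficient to score axis, endpoint, transform and correlation recovery.
#'
#' @param truth [phantom_truth()].
#' @param path JSON path.
#' @return `path` invisibly; `read_phantom_truth()` returns the
#'   [phantom_truth()].
#' @export
write_phantom_truth <- function(truth, path) {
  jsonlite::write_json(list(
    path = list(start = truth$path$start, end = truth$path$end,
                radius = truth$path$radius),
    misalignment = list(rotation = truth$misalignment$rotation,
                        translation = truth$misalignment$translation),
    link = truth$link, noise = truth$noise,
    insertion_offset = truth$insertion_offset, seed = truth$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom_truth
#' @export
read_phantom_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  phantom_truth(drill_path(x$path$start, x$path$end, x$path$radius),
                rigid_transform(x$misalignment$rotation,
                                x$misalignment$translation),
                x$link, x$noise, x$insertion_offset, x$seed)
}
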