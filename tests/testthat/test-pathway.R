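test_that("difference volume is the voxelwise subtraction", {
  ph <- std_phantom_nomis()
  d0 <- difference_volume(ph$volume, ph$volume)
  expect_true(all(d0$data == 0))

  post <- carve_canal(ph$volume, ph$truth)
  d <- difference_volume(ph$volume, post)
  # linearity: a common offset cancels
  pre_c <- ph$volume; pre_c$data <- pre_c$data + 55
  post_c <- post; post_c$data <- post_c$data + 55
  expect_equal(difference_volume(pre_c, post_c)$data, d$data)

  other <- ct_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_error(difference_volume(ph$volume, other), "grid")
})

test_that("canal segmentation keeps the dominant component", {
  ph <- std_phantom_nomis()
  d <- difference_volume(ph$volume, carve_canal(ph$volume, ph$truth))
  vox <- segment_canal(d, 400)
  expect_gte(nrow(vox), 20)

  # the component contains the true axis midpoint
  mid <- (ph$truth$path$start + ph$truth$path$end) / 2
  dists <- sqrt((vox$x - mid[1])^2 + (vox$y - mid[2])^2 +
                  (vox$z - mid[3])^2)
  expect_lt(min(dists), max(d$spacing))

  # threshold above the global maximum -> nothing segmented
  expect_error(segment_canal(d, max(d$data) + 1), "canal not detected")

  # two disjoint blobs: only the larger one is retained
  blob <- ct_volume(array(0, c(40, 40, 40)), spacing = c(1, 1, 1))
  blob$data[5:9, 5:9, 5:9] <- 1000          # 125 voxels
  blob$data[25:27, 25:27, 25:27] <- 1000    # 27 voxels
  v2 <- segment_canal(blob, 500)
  expect_equal(nrow(v2), 125)
  expect_true(all(v2$x <= 9))
  expect_equal(attr(v2, "n_components"), 2)
})

test_that("weighted PCA recovers an exact line and rejects isotropic blobs", {
  z <- seq(0, 30, by = 0.5)
  vox <- tibble::tibble(x = 10, y = 12, z = z, weight = 1)
  p <- estimate_axis_pca(vox, radius = 1)
  expect_equal(abs(sum(path_direction(p) * c(0, 0, 1))), 1,
               tolerance = 1e-12)
  # endpoints at the segment ends (0.5% weighted quantiles of projections)
  ends <- sort(c(p$start[3], p$end[3]))
  expect_lt(abs(ends[1] - 0), 0.5)
  expect_lt(abs(ends[2] - 30), 0.5)

  set.seed(77)
  iso <- tibble::tibble(x = rnorm(500), y = rnorm(500), z = rnorm(500),
                        weight = 1)
  expect_error(estimate_axis_pca(iso), "no dominant axis")
})

test_that("phantom canal axis and endpoints are recovered to sub-voxel", {
  ph <- std_phantom()
  post <- carve_canal(ph$volume, ph$truth)
  undone <- resample_volume(post, invert_transform(ph$truth$misalignment))
  d <- difference_volume(ph$volume, undone)
  p0 <- estimate_axis_pca(segment_canal(d, 400))
  ang <- axis_angle_deg(path_direction(p0), path_direction(ph$truth$path))
  expect_lt(ang, 1)  # noise-free

  p1 <- refine_endpoints(d, p0)
  tol <- 0.5 * max(ph$volume$spacing)
  expect_lt(sqrt(sum((p1$start - ph$truth$path$start)^2)), tol)
  expect_lt(sqrt(sum((p1$end - ph$truth$path$end)^2)), tol)

  # refining an already-correct path changes its length by < 0.2 mm
  p2 <- refine_endpoints(d, ph$truth$path)
  expect_lt(abs(path_length(p2) - path_length(ph$truth$path)), 0.2)
})

test_that("refinement keeps provisional endpoints when no edge is in reach", {
  flat <- ct_volume(array(2000, c(40, 40, 40)), spacing = c(1, 1, 1))
  p <- drill_path(c(10, 20, 20), c(30, 20, 20))
  ws <- testthat::capture_warnings(out <- refine_endpoints(flat, p))
  expect_length(ws, 2)  # both endpoints kept provisional
  expect_match(ws, "provisional", all = TRUE)
  expect_equal(out$start, p$start)
  expect_equal(out$end, p$end)
})

test_that("cylinder mask matches hand-enumerated and analytic volumes", {
  vol <- ct_volume(array(0, c(21, 21, 31)), spacing = c(1, 1, 1))
  # axis along z through voxel centers, radius 1.6 in-plane voxels: per slice
  # the disk holds the center, the 4-neighborhood (distance 1) and the 4
  # diagonals (distance sqrt(2) = 1.414) -> 9 voxels
  p <- drill_path(c(10, 10, 5), c(10, 10, 25), radius = 1.6)
  m <- cylinder_mask(vol, p)
  slice <- m$data[, , 15]
  expect_equal(sum(slice), 9)
  expect_equal(slice[11, 11], 1)  # center (1-based index of world 10)
  expect_equal(slice[12, 12], 1)  # diagonal
  expect_equal(slice[13, 11], 0)  # distance 2

  # voxel count within 15% of pi r^2 L / voxel volume for a long cylinder
  ph <- std_phantom()
  mk <- cylinder_mask(ph$volume, ph$truth$path)
  expected <- pi * ph$truth$path$radius^2 * path_length(ph$truth$path) /
    prod(ph$volume$spacing)
  expect_lt(abs(sum(mk$data) - expected) / expected, 0.15)

  off_axis <- drill_path(c(10.3, 10.4, 5), c(10.3, 10.4, 25), radius = 0.01)
  expect_error(cylinder_mask(vol, off_axis), "empty mask")
})

test_that("profile extraction: homogeneous, two-layer, and step counts", {
  hom <- ct_volume(array(500, c(30, 30, 30)), spacing = c(1, 1, 1))
  p <- drill_path(c(15, 15, 4), c(15, 15, 26))
  prof <- extract_profile(hom, p)
  expect_true(all(prof$hu_mean == 500))
  expect_true(all(prof$hu_min == 500))
  expect_true(all(prof$hu_max == 500))

  # two layers 200 | 1000 with the boundary perpendicular to the axis at
  # z = 15.5; the mean channel must step within 2*ds + 1 voxel of it
  two <- hom
  two$data[, , 1:15] <- 200   # voxel centers z = 0..14
  two$data[, , 16:30] <- 1000 # voxel centers z = 15..29; boundary at 14.5
  prof2 <- extract_profile(two, p)
  bound_s <- 14.5 - 4
  low <- max(prof2$s_mm[prof2$hu_mean <= 250])
  high <- min(prof2$s_mm[prof2$hu_mean >= 950])
  expect_lt(bound_s - low, 2 * 0.1 + 1)
  expect_lt(high - bound_s, 2 * 0.1 + 1)

  # a 29.9 mm path at 0.1 mm steps gives exactly 300 samples
  tall <- ct_volume(array(500, c(24, 24, 40)), spacing = c(1, 1, 1))
  p299 <- drill_path(c(12, 12, 2), c(12, 12, 31.9))
  expect_equal(nrow(extract_profile(tall, p299)), 300)

  # stencil leaving the volume names the arc position
  p_out <- drill_path(c(15, 15, 1), c(15, 15, 29.5))
  expect_error(extract_profile(hom, p_out), "s = ")
})

test_that("profiles commute with global offsets and path reversal", {
  ph <- std_phantom()
  path <- ph$truth$path
  prof <- extract_profile(ph$volume, path)
  off <- ph$volume; off$data <- off$data + 77
  prof_off <- extract_profile(off, path)
  expect_equal(prof_off$hu_mean, prof$hu_mean + 77)
  expect_equal(prof_off$hu_min, prof$hu_min + 77)
  expect_equal(prof_off$hu_max, prof$hu_max + 77)

  # reversal: same samples in reverse order (length snapped to the step grid
  # so both directions sample identical positions)
  u <- path_direction(path)
  L_snap <- floor(path_length(path) / 0.1) * 0.1
  pe <- drill_path(path$start, path$start + L_snap * u, path$radius)
  fwd <- extract_profile(ph$volume, pe)
  bwd <- extract_profile(ph$volume, reverse_path(pe))
  n <- nrow(fwd)
  expect_equal(bwd$hu_mean[n:1], fwd$hu_mean, tolerance = 1e-9)

  # mask is invariant under reversal
  m1 <- cylinder_mask(ph$volume, path)
  m2 <- cylinder_mask(ph$volume, reverse_path(path))
  expect_identical(m1$data, m2$data)
})
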