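test_that("phantom generation is deterministic and has the declared bands", {
  a <- make_phantom(shape = c(48, 48, 48), spacing = c(0.6, 0.6, 0.6),
                    seed = 7)
  b <- make_phantom(shape = c(48, 48, 48), spacing = c(0.6, 0.6, 0.6),
                    seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$path$start, b$truth$path$start)
  expect_identical(a$truth$misalignment$rotation,
                   b$truth$misalignment$rotation)

  # center voxel in the trabecular band, corner in air
  ctr <- sample_volume(a$volume, volume_center(a$volume))
  expect_lt(abs(ctr - 300), 4 * 60)
  expect_equal(a$volume$data[1, 1, 1], -1000)

  # recorded truth sidecar roundtrips
  f <- withr::local_tempfile(fileext = ".json")
  write_phantom_truth(a$truth, f)
  tr <- read_phantom_truth(f)
  expect_equal(tr$path$start, a$truth$path$start)
  expect_equal(tr$misalignment$translation,
               a$truth$misalignment$translation)
  expect_equal(tr$seed, a$truth$seed)
})

test_that("phantom rejects canals that do not fit and bad spacing", {
  expect_error(make_phantom(shape = c(40, 48, 48), seed = 1), "shape")
  expect_error(make_phantom(shape = c(48, 48, 48),
                            spacing = c(0.1, 0.5, 0.5), seed = 1), "spacing")
  bad_path <- drill_path(c(-5, 10, 10), c(30, 10, 10))
  expect_error(make_phantom(shape = c(48, 48, 48),
                            spacing = c(0.5, 0.5, 0.5), seed = 1,
                            path = bad_path), "inside")
})

test_that("carving with zero misalignment equals the carved pre exactly", {
  ph <- std_phantom_nomis()
  post <- carve_canal(ph$volume, ph$truth)
  # probe the axis midpoint: air without noise
  mid <- (ph$truth$path$start + ph$truth$path$end) / 2
  expect_equal(sample_volume(post, mid), -1000)
  # identity misalignment: no resampling happened, grid untouched elsewhere
  far <- ph$volume$data[1:10, 1:10, 1:10]
  expect_identical(post$data[1:10, 1:10, 1:10], far)
})

test_that("positive difference mass concentrates in the true canal tube", {
  ph <- std_phantom()
  post <- carve_canal(ph$volume, ph$truth)
  undone <- resample_volume(post, invert_transform(ph$truth$misalignment))
  d <- difference_volume(ph$volume, undone)
  # above the segmentation threshold; the raw positive part also contains
  # low-amplitude symmetric resampling ripple at every interface
  pos <- which(d$data >= 400)
  vals <- d$data[pos]
  ijk <- arrayInd(pos, dim(d$data)) - 1L
  pts <- sweep(sweep(ijk, 2, d$spacing, `*`), 2, d$origin, `+`)
  u <- path_direction(ph$truth$path)
  rel <- sweep(pts, 2, ph$truth$path$start)
  tax <- as.vector(rel %*% u)
  rad <- sqrt(pmax(0, rowSums(rel^2) - tax^2))
  tube <- rad <= ph$truth$path$radius + max(d$spacing) &
    tax >= -max(d$spacing) & tax <= path_length(ph$truth$path) +
    max(d$spacing)
  expect_gt(sum(vals[tube]) / sum(vals), 0.99)
})

test_that("force simulation is deterministic and noise-free link is exact", {
  ph <- std_phantom_nomis()
  prof <- profile_to_gv(extract_profile(ph$volume,
                                        extend_path(ph$truth$path, 3)))
  tr1 <- simulate_force_trace(prof, ph$truth)
  tr2 <- simulate_force_trace(prof, ph$truth)
  expect_identical(tr1$force_N, tr2$force_N)

  # zero noise: force is an exact monotone (affine) map of the density, so
  # the rank correlation over the canal is 1
  gv_at <- approx(prof$s_mm, prof$gv_mean,
                  xout = prof$s_mm)$y
  fd <- trace_to_displacement(tr1)
  f_at <- approx(fd$x_mm, fd$force_N,
                 xout = prof$s_mm + ph$truth$insertion_offset,
                 rule = 2, ties = "ordered")$y
  in_bone <- prof$s_mm >= 3  # beyond the air pad
  r <- spearman_corr(gv_at[in_bone], f_at[in_bone], method = "t")$r
  expect_equal(r, 1)
})

test_that("with zero link slope the measured correlation is null", {
  ph <- make_phantom(shape = c(48, 48, 48), spacing = c(0.6, 0.6, 0.6),
                     seed = 31,
                     link = list(intercept = 0.5, slope = 0),
                     noise = list(hu_sd = 0, force_sd = 0.2, ar1 = 0.8))
  prof <- profile_to_gv(extract_profile(ph$volume,
                                        extend_path(ph$truth$path, 2)))
  n_keep <- 300
  hits <- 0L
  for (s in 1:200) {
    tr <- simulate_force_trace(prof, ph$truth, seed = 90000 + s)
    fd <- trace_to_displacement(tr)
    f_at <- approx(fd$x_mm, fd$force_N,
                   xout = prof$s_mm + ph$truth$insertion_offset,
                   rule = 2, ties = "ordered")$y
    idx <- seq_len(min(n_keep, nrow(prof)))
    r <- suppressWarnings(stats::cor(prof$gv_mean[idx], f_at[idx],
                                     method = "spearman"))
    if (abs(r) < 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * 200)
})

test_that("target population rho outside (0, 1] is rejected", {
  ph <- std_phantom_nomis()
  prof <- profile_to_gv(extract_profile(ph$volume,
                                        extend_path(ph$truth$path, 3)))
  expect_error(simulate_force_trace(prof, ph$truth, target_rho = 0),
               "rho")
  expect_error(simulate_force_trace(prof, ph$truth, target_rho = 1.2),
               "rho")
})

test_that("carving warns when the radius is below one in-plane voxel", {
  ph <- make_phantom(shape = c(48, 48, 48), spacing = c(0.9, 0.9, 0.9),
                     seed = 8, canal_radius = 0.5,
                     misalignment = rigid_transform())
  expect_warning(carve_canal(ph$volume, ph$truth), "vanish")
})
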