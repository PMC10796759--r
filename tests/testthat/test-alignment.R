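test_that("displacement conversion follows x = v t", {
  tr <- force_trace((0:999) / 1000, rep(0.5, 1000), feed_velocity = 2)
  fd <- trace_to_displacement(tr)
  expect_equal(nrow(fd), 1000)
  expect_equal(max(fd$x_mm), 2 * 0.999)
  expect_equal(diff(fd$x_mm)[1], 0.002)

  # 120 mm/min equals 2 mm/s to machine precision
  tr2 <- force_trace((0:999) / 1000, rep(0.5, 1000),
                     feed_velocity = 120 / 60)
  expect_identical(trace_to_displacement(tr2)$x_mm, fd$x_mm)

  # doubling the velocity doubles every displacement
  tr3 <- force_trace((0:999) / 1000, rep(0.5, 1000), feed_velocity = 4)
  expect_equal(trace_to_displacement(tr3)$x_mm, 2 * fd$x_mm)
})

test_that("insertion onset lands on a clean step and resists noise", {
  x <- (0:199) / 10
  y <- c(rep(0, 100), rep(1, 100))
  on <- detect_insertion(x, y)
  expect_lt(abs(on - x[101]), x[2] - x[1])  # within one sample of the step

  set.seed(51)
  hits <- 0L
  for (i in 1:100) {
    yn <- y + rnorm(200, 0, 0.02)
    on_i <- detect_insertion(x, yn)
    if (abs(on_i - x[101]) <= 5 * 0.1) hits <- hits + 1L
  }
  expect_equal(hits, 100L)

  expect_error(detect_insertion(x, rep(0, 200)), "no insertion")
  expect_error(detect_insertion(x[1:30], y[1:30]), "too short")
})

test_that("self-alignment recovers a known 1.3 mm shift with r = 1", {
  set.seed(52)
  s <- (0:299) / 10
  base <- cumsum(rnorm(300))^0  # placeholder, replaced below
  intensity <- c(rep(0, 40), 50 + 30 * sin((1:260) / 15) + (1:260) / 10)
  prof <- tibble::tibble(s_mm = s, gv_max = intensity)
  shift_true <- 1.3
  fx <- seq(0, 40, by = 0.002)
  fy <- approx(s + shift_true, intensity, xout = fx, rule = 2)$y
  pair <- align_pair(prof, tibble::tibble(x_mm = fx, force_N = fy))
  expect_lt(abs(attr(pair, "shift_mm") - shift_true), 0.1)
  expect_equal(spearman_corr(pair$intensity_norm, pair$force_norm,
                             method = "t")$r, 1, tolerance = 1e-9)
})

test_that("shift recovery holds across offsets at 5% force noise", {
  ph <- std_phantom_nomis()
  prof0 <- profile_to_gv(extract_profile(ph$volume,
                                         extend_path(ph$truth$path, 3)))
  truth <- ph$truth
  set.seed(53)
  for (s0 in c(0.5, 1, 2, 5)) {
    truth$insertion_offset <- s0
    truth$noise$force_sd <- 0.05 * 5  # 5% of the ~5 N range
    truth$noise$ar1 <- 0.8
    tr <- simulate_force_trace(prof0, truth, seed = 6000 + round(10 * s0))
    pair <- align_pair(prof0, trace_to_displacement(tr), channel = "gv_mean")
    expect_lt(abs(attr(pair, "shift_mm") - s0), max(0.1, 0.15))
  }
})

test_that("alignment preserves order and fails on tiny overlap", {
  ph <- std_phantom_nomis()
  prof <- profile_to_gv(extract_profile(ph$volume,
                                        extend_path(ph$truth$path, 3)))
  tr <- simulate_force_trace(prof, ph$truth)
  pair <- align_pair(prof, trace_to_displacement(tr), channel = "gv_mean")
  expect_true(all(diff(pair$s_mm) > 0))
  expect_true(all(pair$intensity_norm >= 0 & pair$intensity_norm <= 1))
  expect_true(all(pair$force_norm >= 0 & pair$force_norm <= 1))

  fd <- trace_to_displacement(tr)
  short <- fd[fd$x_mm <= ph$truth$insertion_offset + 2.9, ]
  expect_error(align_pair(prof, short, channel = "gv_mean",
                          cfg_force = insertion_config(sustain_samples = 3)),
               "overlap")
})

test_that("correlation is invariant to which series carries the shift", {
  ph <- std_phantom_nomis()
  prof <- profile_to_gv(extract_profile(ph$volume,
                                        extend_path(ph$truth$path, 3)))
  tr <- simulate_force_trace(prof, ph$truth)
  fd <- trace_to_displacement(tr)
  pair_a <- align_pair(prof, fd, channel = "gv_mean")
  # shift the profile arc axis instead: same overlap, same correlation
  prof_b <- prof
  prof_b$s_mm <- prof_b$s_mm + 2.2
  pair_b <- align_pair(prof_b, fd, channel = "gv_mean")
  ra <- spearman_corr(pair_a$intensity_norm, pair_a$force_norm,
                      method = "t")$r
  rb <- spearman_corr(pair_b$intensity_norm, pair_b$force_norm,
                      method = "t")$r
  expect_equal(ra, rb, tolerance = 1e-9)
})
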