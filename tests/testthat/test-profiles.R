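test_that("HU to GV conversion anchors, clamps, and converts profiles", {
  expect_equal(hu_to_gv(-1025), 1)
  expect_equal(hu_to_gv(-2000), 0)
  expect_equal(hu_to_gv(0), 1026)
  expect_equal(hu_to_gv(4000), 4096)

  prof <- tibble::tibble(s_mm = 0:2 / 10, hu_mean = c(-1025, 0, 100),
                         hu_min = c(-1100, -10, 90),
                         hu_max = c(-1000, 10, 110))
  g <- profile_to_gv(prof)
  expect_equal(g$gv_mean, c(1, 1026, 1126))
  expect_equal(g$gv_max, c(26, 1036, 1136))
})

test_that("windowed stats match a hand-computed case and truncate at ends", {
  prof <- tibble::tibble(s_mm = (0:4) / 10,
                         hu_mean = c(0, 1, 2, 3, 4),
                         hu_min = c(0, 1, 2, 3, 4),
                         hu_max = c(0, 1, 2, 3, 4))
  w <- windowed_stats(prof, 0.2)
  expect_equal(w$hu_max[3], 4)         # window {0..4}
  expect_equal(w$hu_mean[1], 1)        # truncated window {0,1,2}
  expect_equal(w$hu_min[5], 2)         # truncated window {2,3,4}

  # constant profile: all channels stay constant
  cp <- tibble::tibble(s_mm = (0:9) / 10, hu_mean = rep(7, 10),
                       hu_min = rep(7, 10), hu_max = rep(7, 10))
  wc <- windowed_stats(cp, 0.2)
  expect_true(all(wc$hu_mean == 7) && all(wc$hu_min == 7) &&
                all(wc$hu_max == 7))

  # half-width below half a step: singleton windows, output equals input
  w0 <- windowed_stats(prof, 0.04)
  expect_equal(w0$hu_mean, prof$hu_mean)
  expect_equal(w0$hu_max, prof$hu_max)

  expect_error(windowed_stats(prof[0, ], 0.2), "non-empty")
})

test_that("windowed stats equal the brute-force window scan exactly", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:120, 1)
    ds <- sample(c(0.05, 0.1, 0.2), 1)
    hw <- sample(c(0.1, 0.2, 0.35), 1)
    x <- rnorm(n)
    prof <- tibble::tibble(s_mm = (seq_len(n) - 1) * ds, hu_mean = x,
                           hu_min = x, hu_max = x)
    w <- windowed_stats(prof, hw)
    # independent O(n * w) oracle straight from the definition
    for (ch in c("min", "max", "mean")) {
      fun <- match.fun(ch)
      oracle <- vapply(seq_len(n), function(j) {
        fun(x[abs(prof$s_mm - prof$s_mm[j]) <= hw + 1e-12])
      }, numeric(1))
      expect_identical(w[[paste0("hu_", ch)]], oracle)
    }
  }
})

test_that("window filter is monotone in its input", {
  set.seed(43)
  for (i in 1:20) {
    a <- rnorm(50)
    b <- a - abs(rnorm(50))  # b <= a elementwise
    pa <- tibble::tibble(s_mm = (0:49) / 10, hu_mean = a, hu_min = a,
                         hu_max = a)
    pb <- tibble::tibble(s_mm = (0:49) / 10, hu_mean = b, hu_min = b,
                         hu_max = b)
    wa <- windowed_stats(pa, 0.2)
    wb <- windowed_stats(pb, 0.2)
    expect_true(all(wa$hu_max >= wb$hu_max))
    expect_true(all(wa$hu_mean >= wb$hu_mean))
    expect_true(all(wa$hu_min >= wb$hu_min))
  }
})

test_that("min-max normalization rescales and preserves order", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(44)
  x <- rnorm(60)
  expect_equal(spearman_corr(x, normalize_minmax(x), method = "t")$r, 1)
  expect_error(normalize_minmax(c(5, 5, 5)), "zero range")
})

test_that("correlations are invariant to GV offset and normalization", {
  set.seed(45)
  for (i in 1:100) {
    n <- sample(30:200, 1)
    hu <- rnorm(n, 200, 300)
    y <- 0.4 * hu + rnorm(n, 0, 150)
    r0 <- spearman_corr(hu, y, method = "t")$r
    # unclamped affine GV map with an arbitrary offset
    r1 <- spearman_corr(hu_to_gv(hu, offset = 2000,
                                 clamp_range = c(-1e9, 1e9)), y,
                        method = "t")$r
    r2 <- spearman_corr(normalize_minmax(hu), normalize_minmax(y),
                        method = "t")$r
    expect_lt(abs(r1 - r0), 1e-12)
    expect_lt(abs(r2 - r0), 1e-12)
    # Pearson r is invariant under both affine maps too
    p0 <- pearson_fit(hu, y)$r
    p1 <- pearson_fit(hu_to_gv(hu, offset = 2000,
                               clamp_range = c(-1e9, 1e9)),
                      normalize_minmax(y))$r
    expect_lt(abs(p1 - p0), 1e-12)
  }
})
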