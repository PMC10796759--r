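test_that("Spearman r matches hand and reference computations", {
  expect_equal(spearman_corr(1:3, c(10, 20, 30), method = "t")$r, 1)
  # sum d^2 = 2 -> r = 1 - 6*2 / (4 * 15) = 0.8
  expect_equal(spearman_corr(1:4, c(1, 3, 2, 4))$r, 0.8)
  x <- c(0.3, 1.2, 5, 9.1)
  expect_equal(spearman_corr(x, rev(x))$r, -1)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")

  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    a <- rnorm(n); b <- 0.5 * a + rnorm(n)
    expect_equal(spearman_corr(a, b, method = "t")$r,
                 cor(a, b, method = "spearman"))
    ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                    exact = FALSE))
    expect_equal(spearman_corr(a, b, method = "t")$p, ct$p.value,
                 tolerance = 1e-8)
  }
})

test_that("exact permutation p agrees with the t approximation at small n", {
  set.seed(62)
  for (i in 1:50) {
    n <- sample(8:9, 1)
    a <- rnorm(n); b <- rnorm(n)
    pe <- spearman_corr(a, b, method = "exact")$p
    pt_ <- spearman_corr(a, b, method = "t")$p
    expect_lt(abs(pe - pt_), 0.02)
  }
  # exact route refuses large n
  expect_error(spearman_corr(rnorm(12), rnorm(12), method = "exact"),
               "n <= 9")
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(63)
  for (i in 1:20) {
    a <- rnorm(40); b <- rnorm(40)
    r0 <- spearman_corr(a, b, method = "t")$r
    expect_equal(spearman_corr(exp(a), b, method = "t")$r, r0)
    expect_equal(spearman_corr(a, qlogis(plogis(b))^3 + b, method = "t")$r,
                 r0)
  }
})

test_that("Pearson fit returns the closed-form least squares line", {
  f <- pearson_fit(c(0, 1, 2, 3), c(1, 3, 5, 7))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$R2, 1)
  expect_equal(pearson_fit(1:10, 2 * (1:10) + 3)$r, 1)

  # orthogonal construction: zero sample covariance
  x <- c(-1, 0, 1)
  y <- c(1, -2, 1)
  expect_equal(pearson_fit(x, y)$r, 0)

  set.seed(64)
  a <- rnorm(30); b <- rnorm(30)
  fit <- pearson_fit(a, b)
  lmfit <- lm(b ~ a)
  expect_equal(fit$slope, unname(coef(lmfit)[2]))
  expect_equal(fit$intercept, unname(coef(lmfit)[1]))
  expect_equal(fit$R2, summary(lmfit)$r.squared)
  expect_error(pearson_fit(rep(2, 5), 1:5), "constant")
})

test_that("strength classes follow the adapted bands with closed left edges", {
  expect_equal(as.character(classify_r(0.721)), "moderately_strong")
  expect_equal(as.character(classify_r(0.107)), "poor")
  expect_equal(as.character(classify_r(0.3)), "fair")
  expect_equal(as.character(classify_r(0.6)), "moderately_strong")
  expect_equal(as.character(classify_r(0.8)), "very_strong")
  expect_equal(as.character(classify_r(-0.75)), "moderately_strong")
  expect_error(classify_r(1.2), "<= 1")
})

test_that("class tallies reproduce the reference narrative", {
  ref <- specimen_correlations()
  tal <- count_by_class(ref)
  expect_equal(tal$count[tal$class == "poor"], 2L)
  expect_equal(tal$count[tal$class == "fair"], 5L)
  expect_equal(tal$count[tal$class == "moderately_strong"], 5L)
  expect_equal(tal$count[tal$class == "very_strong"], 0L)
  expect_equal(sum(tal$count), 12L)  # significant specimens only

  # relaxing the filter re-admits the one non-significant (poor) specimen
  tal1 <- count_by_class(ref, significance_filter = 1.0)
  expect_equal(tal1$count[tal1$class == "poor"], 3L)

  none <- count_by_class(ref, significance_filter = 1e-9)
  expect_true(all(none$count == 0L))
})

test_that("pooled pair counts add up by region, individual and overall", {
  ref <- specimen_correlations()
  pc <- pooled_pair_counts(ref)
  get <- function(gt, ind = NA, reg = NA) {
    row <- pc[pc$group_type == gt &
                (is.na(ind) | pc$individual %in% ind) &
                (is.na(reg) | pc$region %in% reg), ]
    row$n[1]
  }
  expect_equal(get("overall"), 4818L)
  expect_equal(get("region", reg = "T"), 904L)
  expect_equal(get("region", reg = "L"), 3914L)
  expect_equal(get("individual", ind = "A"), 2620L)
  expect_equal(get("individual", ind = "B"), 2198L)
  expect_equal(get("region_individual", ind = "B", reg = "T"), 309L)
  # thoracic subtotal is the sum of its three members
  expect_equal(sum(ref$n[ref$region == "T"]), 904L)
})

test_that("grouped correlations pool by concatenation with additive n", {
  set.seed(65)
  mk_pair <- function(ind, reg, lev, n, rho) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    p <- tibble::tibble(s_mm = (seq_len(n) - 1) / 10,
                        intensity_norm = normalize_minmax(x),
                        force_norm = normalize_minmax(y))
    attr(p, "meta") <- specimen_meta(ind, reg, lev)
    attr(p, "length_mm") <- n / 10
    attr(p, "n") <- n
    class(p) <- c("aligned_pair", class(p))
    p
  }
  pairs <- list(mk_pair("A", "T", "T11", 120, 0.7),
                mk_pair("A", "L", "L2", 150, 0.4),
                mk_pair("B", "L", "L3", 130, 0.2))
  res <- suppressWarnings(grouped_correlations(pairs))
  spec <- res[res$group_type == "specimen", ]
  expect_equal(nrow(spec), 3)
  expect_equal(res$n[res$group_type == "overall"], 400L)
  expect_equal(res$n[res$group_type == "region" & res$region == "L"], 280L)
  # a single-member group equals its specimen result
  solo <- res[res$group_type == "region" & res$region == "T", ]
  expect_equal(solo$r_spearman, spec$r_spearman[spec$level == "T11"],
               tolerance = 1e-12)
  # determinism
  res2 <- suppressWarnings(grouped_correlations(pairs))
  expect_identical(res$r_spearman, res2$r_spearman)
})

test_that("correlate_pair carries metadata into tidy()/glance()", {
  set.seed(66)
  x <- rnorm(80)
  p <- tibble::tibble(s_mm = (0:79) / 10,
                      intensity_norm = normalize_minmax(x),
                      force_norm = normalize_minmax(x + rnorm(80, 0, 0.5)))
  attr(p, "meta") <- specimen_meta("A", "T", "T12")
  attr(p, "length_mm") <- 8
  class(p) <- c("aligned_pair", class(p))
  cor <- correlate_pair(p)
  td <- tidy(cor)
  expect_equal(td$level, "T12")
  expect_equal(td$n, 80L)
  gl <- glance(cor)
  expect_equal(gl$r_spearman, cor$r_spearman)
  expect_s3_class(autoplot(p), "ggplot")
})
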