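#' Spearman rank correlation with significance
#'
#' Spearman's r is the Pearson correlation of average-ranked data (ties get
#' average ranks). The two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom for
#' n > 9, and an exact permutation distribution of |r| for n <= 9 (all n!
#' orderings are enumerated). `method` can force either route.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @param method `"auto"` (exact for n <= 9), `"t"`, or `"exact"`.
#' @return List with `r`, `p`, `n`, `method`.
#' @examples
#' spearman_corr(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
spearman_corr <- function(x, y, method = c("auto", "t", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  if (n != length(y) || n < 3)
    rlang::abort("need equal-length inputs with n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    rlang::abort("inputs must be finite")
  if (min(x) == max(x) || min(y) == max(y))
    rlang::abort("undefined ranks: constant input")
  rx <- rank(x); ry <- rank(y)
  r <- rank_pearson(rx, ry)
  if (method == "auto") method <- if (n <= 9) "exact" else "t"
  p <- if (method == "t") {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    if (n > 9)
      rlang::abort("exact permutation p is only enumerated for n <= 9")
    perms <- permutations_all(n)
    rperm <- as.vector(perms_r(rx, ry, perms))
    mean(abs(rperm) >= abs(r) - 1e-12)
  }
  list(r = r, p = min(1, p), n = n, method = method)
}

rank_pearson <- function(rx, ry) {
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

# All permutations of 1..n as an n! x n matrix (lexicographic, recursive).
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Correlation of rx with every permutation of ry.
perms_r <- function(rx, ry, perms) {
  n <- length(rx)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  ym <- matrix(ryc[perms], nrow(perms), n)
  (ym %*% rxc) / denom
}

#' Pearson correlation and least-squares line
#'
#' @param x,y Numeric vectors, n >= 3, neither constant.
#' @return List with `r`, `R2` (= r^2), `slope`, `intercept`, `p` (two-sided
#'   t-test on r) and `n`.
#' @export
pearson_fit <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3)
    rlang::abort("need equal-length inputs with n >= 3")
  if (min(x) == max(x) || min(y) == max(y))
    rlang::abort("constant input: Pearson correlation undefined")
  xc <- x - mean(x); yc <- y - mean(y)
  sxy <- sum(xc * yc)
  r <- sxy / sqrt(sum(xc^2) * sum(yc^2))
  slope <- sxy / sum(xc^2)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, R2 = r^2, slope = slope,
       intercept = mean(y) - slope * mean(x),
       p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Correlation strength classification (Chan-adapted bands)
#'
#' Bands on |r|: below 0.3 poor, 0.3 to below 0.6 fair, 0.6 to below 0.8
#' moderately strong, 0.8 and above very strong. Boundaries are left-closed
#' (r = 0.3 is fair).
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @return Factor with levels `poor`, `fair`, `moderately_strong`,
#'   `very_strong`.
#' @examples
#' classify_r(c(0.107, 0.3, 0.721, 0.85))
#' @export
classify_r <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) rlang::abort("|r| must be <= 1")
  cut(pmin(abs(r), 1), breaks = c(-Inf, 0.3, 0.6, 0.8, Inf),
      labels = c("poor", "fair", "moderately_strong", "very_strong"),
      right = FALSE)
}

#' Correlate one aligned force-density pair
#'
#' @param pair An `aligned_pair` from [align_pair()].
#' @return Object of class `force_density_cor` with Spearman and Pearson
#'   results, the strength class, metadata and pair count. Has [tidy()] and
#'   [glance()] methods.
#' @export
correlate_pair <- function(pair) {
  sp <- spearman_corr(pair$intensity_norm, pair$force_norm,
                      method = if (nrow(pair) <= 9) "exact" else "t")
  pe <- pearson_fit(pair$intensity_norm, pair$force_norm)
  structure(list(n = sp$n, r_spearman = sp$r, p = sp$p, r_pearson = pe$r,
                 R2 = pe$R2, slope = pe$slope, intercept = pe$intercept,
                 class = as.character(classify_r(sp$r)),
                 significant = sp$p <= 0.01,
                 meta = attr(pair, "meta"),
                 length_mm = attr(pair, "length_mm"),
                 shift_mm = attr(pair, "shift_mm")),
            class = "force_density_cor")
}

#' @export
print.force_density_cor <- function(x, ...) {
  m <- x$meta
  lab <- if (!is.null(m)) sprintf(" [%s %s]", m$individual, m$level) else ""
  cat(sprintf("<force_density_cor>%s n = %d, Spearman r = %.3f (p = %.3g, %s), Pearson R2 = %.3f\n",
              lab, x$n, x$r_spearman, x$p, x$class, x$R2))
  invisible(x)
}

result_row <- function(cor, group_type, individual = NA_character_,
                       region = NA_character_, level = NA_character_) {
  tibble::tibble(group_type = group_type, individual = individual,
                 region = region, level = level, n = cor$n,
                 r_spearman = cor$r_spearman, p = cor$p,
                 r_pearson = cor$r_pearson, R2 = cor$R2,
                 class = cor$class, significant = cor$significant,
                 length_mm = if (is.null(cor$length_mm)) NA_real_
                             else cor$length_mm)
}

#' Grouped correlation table
#'
#' Computes one correlation per specimen plus pooled correlations per region
#' (T/L), per individual, per region-by-individual, and overall. Pooling
#' concatenates the per-specimen normalized pairs; pooled n is the sum of
#' member pair counts. Pooled rows have no pathway length.
#'
#' @param pairs List of `aligned_pair` objects with complete
#'   [specimen_meta()] attached.
#' @return Tibble with columns `group_type` (`specimen`, `region`,
#'   `individual`, `region_individual`, `overall`), the group labels, `n`,
#'   `r_spearman`, `p`, `r_pearson`, `R2`, `class`, `significant`,
#'   `length_mm`.
#' @export
grouped_correlations <- function(pairs) {
  if (length(pairs) == 0) rlang::abort("need at least one aligned pair")
  metas <- lapply(pairs, attr, "meta")
  if (any(vapply(metas, is.null, TRUE)))
    rlang::abort("every pair needs specimen metadata for grouping")

  spec_rows <- purrr::map2_dfr(pairs, metas, function(p, m) {
    result_row(correlate_pair(p), "specimen", m$individual, m$region, m$level)
  })

  pool <- function(sel, group_type, individual = NA, region = NA) {
    sub <- pairs[sel]
    if (length(sub) == 0) {
      rlang::warn(sprintf("empty group skipped (%s %s%s)", group_type,
                          if (is.na(individual)) "" else individual,
                          if (is.na(region)) "" else region))
      return(NULL)
    }
    xi <- unlist(lapply(sub, `[[`, "intensity_norm"))
    xf <- unlist(lapply(sub, `[[`, "force_norm"))
    sp <- spearman_corr(xi, xf, method = "t")
    pe <- pearson_fit(xi, xf)
    cor <- list(n = sp$n, r_spearman = sp$r, p = sp$p, r_pearson = pe$r,
                R2 = pe$R2, class = as.character(classify_r(sp$r)),
                significant = sp$p <= 0.01, length_mm = NULL)
    result_row(cor, group_type, as.character(individual),
               as.character(region))
  }

  region_of <- vapply(metas, `[[`, "", "region")
  indiv_of <- vapply(metas, `[[`, "", "individual")
  rows <- list(spec_rows)
  for (rg in unique(region_of))
    rows <- c(rows, list(pool(region_of == rg, "region", region = rg)))
  for (id in unique(indiv_of))
    rows <- c(rows, list(pool(indiv_of == id, "individual",
                              individual = id)))
  for (id in unique(indiv_of))
    for (rg in unique(region_of))
      rows <- c(rows, list(pool(indiv_of == id & region_of == rg,
                                "region_individual", individual = id,
                                region = rg)))
  rows <- c(rows, list(pool(rep(TRUE, length(pairs)), "overall")))
  dplyr::bind_rows(rows)
}

#' Tally correlation strength classes among significant specimens
#'
#' Re-classifies the per-specimen Spearman coefficients, drops results with
#' `p > significance_filter` (default 0.01), and counts specimens per class.
#'
#' @param results Data frame with columns `r_spearman` and `p` (rows with
#'   `group_type != "specimen"` are ignored if that column is present).
#' @param significance_filter Keep rows with `p <= significance_filter`.
#' @return Tibble with `class` and `count` for all four classes (zeros kept).
#' @export
count_by_class <- function(results, significance_filter = 0.01) {
  df <- results
  if ("group_type" %in% names(df))
    df <- dplyr::filter(df, .data$group_type == "specimen")
  df <- dplyr::filter(df, .data$p <= significance_filter)
  cls <- classify_r(df$r_spearman)
  tibble::tibble(class = levels(cls),
                 count = as.integer(table(cls)[levels(cls)]))
}

#' Reference per-specimen correlation table
#'
#' A bundled reference tabulation from a cadaveric drilling experiment on two
#' donors (A, B): for each of 13 thoraco-lumbar vertebrae the Spearman
#' correlation between the drilled-canal gray-value profile and the drilling
#' force, the Pearson coefficient of determination, the significance level
#' (p-values printed as "< 0.001" are stored as the upper bound 0.001), the
#' number of aligned pairs and the drilled pathway length. Used as a worked
#' input for [count_by_class()] and the pooled-count tabulations.
#'
#' @return Tibble with columns `individual`, `region`, `level`, `r_spearman`,
#'   `R2`, `p`, `n`, `length_mm`.
#' @examples
#' ref <- specimen_correlations()
#' sum(ref$n)  # total aligned pairs across all specimens
#' count_by_class(ref)
#' @export
specimen_correlations <- function() {
  path <- system.file("extdata", "specimen_correlations.csv",
                      package = "drillprofile", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Pooled pair counts by grouping
#'
#' Sums aligned-pair counts over specimens: overall, per region, per
#' individual, and per region-by-individual.
#'
#' @param specimens Data frame with columns `individual`, `region`, `n` (e.g.
#'   [specimen_correlations()] or the specimen rows of
#'   [grouped_correlations()]).
#' @return Tibble with `group_type`, `individual`, `region`, `n`.
#' @export
pooled_pair_counts <- function(specimens) {
  overall <- tibble::tibble(group_type = "overall",
                            individual = NA_character_,
                            region = NA_character_, n = sum(specimens$n))
  by_region <- specimens |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(group_type = "region", individual = NA_character_)
  by_indiv <- specimens |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(group_type = "individual", region = NA_character_)
  by_both <- specimens |>
    dplyr::group_by(.data$individual, .data$region) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(group_type = "region_individual")
  dplyr::bind_rows(overall, by_region, by_indiv, by_both) |>
    dplyr::select("group_type", "individual", "region", "n")
}
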