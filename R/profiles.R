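#' Hounsfield-unit to gray-value conversion
#'
#' Gray values (GV) are an offset-shifted copy of the HU scale clamped to the
#' scanner's stored range: `gv = clamp(hu + offset, range)`. The default
#' offset 1026 anchors -1025 HU at 1 GV with unit slope, and the default range
#' is `[0, 4096]`. Because the map is affine and rank-preserving wherever values
#' are unclamped, all downstream Spearman (and, off the clamp, Pearson)
#' correlations are insensitive to the offset choice.
#'
#' @param hu Numeric HU values (vector or array).
#' @param offset GV offset (default 1026).
#' @param clamp_range Length-2 clamp interval (default `c(0, 4096)`).
#' @return Gray values, same shape as `hu`.
#' @examples
#' hu_to_gv(c(-1025, -2000, 0))  # 1, 0 (clamped), 1026
#' @export
hu_to_gv <- function(hu, offset = 1026, clamp_range = c(0, 4096)) {
  if (any(!is.finite(hu))) rlang::abort("HU values must be finite")
  pmin(clamp_range[2], pmax(clamp_range[1], hu + offset))
}

#' Convert the channels of a density profile to gray values
#'
#' Adds `gv_mean`, `gv_min`, `gv_max` columns from the HU channels.
#'
#' @param profile A `density_profile` from [extract_profile()].
#' @inheritParams hu_to_gv
#' @return The profile with gray-value channels appended.
#' @export
profile_to_gv <- function(profile, offset = 1026, clamp_range = c(0, 4096)) {
  for (ch in c("mean", "min", "max")) {
    hu <- profile[[paste0("hu_", ch)]]
    if (!is.null(hu))
      profile[[paste0("gv_", ch)]] <- hu_to_gv(hu, offset, clamp_range)
  }
  profile
}

#' Sliding min/max/mean window filter
#'
#' For each arc position, takes all samples within `half_width` mm (a total
#' window of 2 * half_width; windows are truncated at the profile ends, the
#' output length is unchanged) and records the window minimum, maximum and
#' arithmetic mean. Applied to the min/max/mean channels respectively: the
#' windowed maximum is the running max of the per-step maxima, and likewise
#' for min and mean.
#'
#' @param profile A `density_profile` (uniform in `s_mm`).
#' @param half_width Window half-width in mm (default 0.2, i.e. a 0.4 mm
#'   window).
#' @return The profile with the same columns, channels replaced by their
#'   windowed versions.
#' @export
windowed_stats <- function(profile, half_width = 0.2) {
  if (!is.data.frame(profile) || nrow(profile) == 0)
    rlang::abort("`profile` must be a non-empty profile")
  if (half_width <= 0) rlang::abort("`half_width` must be > 0")
  s <- profile$s_mm
  n <- length(s)
  ds <- if (n > 1) s[2] - s[1] else 1
  k <- floor(half_width / ds + 1e-9)
  out <- profile
  win_apply <- function(x, fun) {
    vapply(seq_len(n), function(i) {
      fun(x[max(1, i - k):min(n, i + k)])
    }, numeric(1))
  }
  for (ch in grep("^(hu|gv)_min$", names(profile), value = TRUE))
    out[[ch]] <- win_apply(profile[[ch]], min)
  for (ch in grep("^(hu|gv)_max$", names(profile), value = TRUE))
    out[[ch]] <- win_apply(profile[[ch]], max)
  for (ch in grep("^(hu|gv)_mean$", names(profile), value = TRUE))
    out[[ch]] <- win_apply(profile[[ch]], mean)
  out
}

#' Min-max normalization
#'
#' Rescales a series to `[0, 1]`: `(x - min) / (max - min)`. Order-preserving,
#' so rank-based statistics are unchanged.
#'
#' @param x Numeric series with `min(x) < max(x)`.
#' @return Normalized series in `[0, 1]`.
#' @export
normalize_minmax <- function(x) {
  if (any(!is.finite(x))) rlang::abort("series must be finite")
  r <- range(x)
  if (r[1] >= r[2]) rlang::abort("zero range: cannot normalize a constant series")
  (x - r[1]) / (r[2] - r[1])
}
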