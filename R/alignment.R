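#' Convert a force trace to force-vs-displacement
#'
#' At constant feed velocity the drill tip displacement is `x = v * t`; at the
#' default 2 mm/s and 1 kHz this is one sample every 0.002 mm.
#'
#' @param trace A [force_trace()].
#' @return Tibble with columns `x_mm` and `force_N`.
#' @export
trace_to_displacement <- function(trace) {
  v <- attr(trace, "feed_velocity")
  if (is.null(v) || v <= 0)
    rlang::abort("trace must carry a positive feed_velocity")
  tibble::tibble(x_mm = v * trace$time_s, force_N = trace$force_N)
}

#' Insertion-onset detection settings
#'
#' The insertion point is where the series first leaves its baseline: the
#' baseline is the mean of the first `baseline_fraction` of samples, and the
#' onset is the first position where the value exceeds
#' `baseline + rise_threshold_fraction * (max - baseline)` for
#' `sustain_samples` consecutive samples.
#'
#' @param baseline_fraction Fraction of leading samples forming the baseline
#'   (default 0.05; must be < 0.5).
#' @param rise_threshold_fraction Rise threshold as a fraction of the range
#'   above baseline (default 0.05).
#' @param sustain_samples Consecutive samples required above threshold
#'   (default 3).
#' @return A list of class `insertion_config`.
#' @export
insertion_config <- function(baseline_fraction = 0.05,
                             rise_threshold_fraction = 0.05,
                             sustain_samples = 3) {
  if (baseline_fraction <= 0 || baseline_fraction >= 0.5)
    rlang::abort("`baseline_fraction` must be in (0, 0.5)")
  if (rise_threshold_fraction <= 0)
    rlang::abort("`rise_threshold_fraction` must be > 0")
  if (sustain_samples < 1)
    rlang::abort("`sustain_samples` must be >= 1")
  structure(list(baseline_fraction = baseline_fraction,
                 rise_threshold_fraction = rise_threshold_fraction,
                 sustain_samples = as.integer(sustain_samples)),
            class = "insertion_config")
}

#' Detect the insertion point of a series
#'
#' Finds the first sustained rise above baseline (see [insertion_config()])
#' and returns the threshold-crossing position with sub-sample precision
#' (linear interpolation between the last sub-threshold and first
#' supra-threshold sample).
#'
#' @param x Positions (mm), strictly increasing; or a two-column data frame
#'   (positions, values) with `y` missing.
#' @param y Series values.
#' @param cfg An [insertion_config()].
#' @return Onset position in the units of `x`.
#' @export
detect_insertion <- function(x, y = NULL, cfg = insertion_config()) {
  if (is.null(y)) {
    stopifnot(is.data.frame(x), ncol(x) >= 2)
    y <- x[[2]]; x <- x[[1]]
  }
  n <- length(y)
  if (n < 20 * cfg$sustain_samples)
    rlang::abort("series too short for insertion detection")
  nb <- max(1L, floor(cfg$baseline_fraction * n))
  baseline <- mean(y[seq_len(nb)])
  thr <- baseline + cfg$rise_threshold_fraction * (max(y) - baseline)
  above <- y > thr
  k <- cfg$sustain_samples
  sustained <- above
  if (k > 1) {
    run <- stats::filter(as.numeric(above), rep(1, k), sides = 1)
    sustained <- c(rep(FALSE, k - 1), run[-seq_len(k - 1)] == k)
    # sustained[i] TRUE when samples i-k+1 .. i are all above; onset index is
    # the start of the first full run
    first_run_end <- which(sustained)[1]
    i <- if (is.na(first_run_end)) NA_integer_ else first_run_end - k + 1L
  } else {
    i <- which(above)[1]
  }
  if (is.na(i)) rlang::abort("no insertion detected")
  if (i == 1L) return(x[1])
  if (y[i] <= y[i - 1] || y[i - 1] > thr) return(x[i])
  x[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
}

# Onset of a densely sampled force record with autocorrelated noise: coarse
# detection on block means (robust), then sub-sample refinement at the raw
# threshold crossing nearest the coarse onset. On a noise-free record the
# refined crossing is the exact one, so alignment stays exact.
detect_force_onset <- function(x, y, cfg, ds_prof) {
  dx <- stats::median(diff(x))
  block <- max(1L, round(ds_prof / dx / 2))
  if (block == 1L) return(detect_insertion(x, y, cfg))
  nb <- floor(length(y) / block)
  ym <- colMeans(matrix(y[seq_len(nb * block)], nrow = block))
  xm <- colMeans(matrix(x[seq_len(nb * block)], nrow = block))
  coarse <- detect_insertion(xm, ym, cfg)
  # threshold defined exactly as detect_insertion defines it on the raw series
  nb0 <- max(1L, floor(cfg$baseline_fraction * length(y)))
  baseline <- mean(y[seq_len(nb0)])
  thr <- baseline + cfg$rise_threshold_fraction * (max(y) - baseline)
  win <- which(x >= coarse - 2 * ds_prof & x <= coarse + 2 * ds_prof)
  if (length(win) >= 2) {
    yw <- y[win]
    up <- which(yw[-1] > thr & yw[-length(yw)] <= thr) + 1L
    if (length(up)) {
      i <- win[up[which.min(abs(x[win[up]] - coarse))]]
      if (i > 1 && y[i] > y[i - 1])
        return(x[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) *
                 (x[i] - x[i - 1]))
    }
  }
  coarse
}

#' Align a density profile with a force-displacement series
#'
#' Detects the insertion point in both series, shifts the force axis so the
#' onsets coincide, linearly interpolates the force onto the profile's arc
#' grid over the overlap, restricts to the in-bone segment (arc positions at
#' or beyond the intensity onset; the pre-contact air segment carries no
#' signal), and min-max normalizes both channels.
#'
#' @param profile A `density_profile`; the correlation channel is selected by
#'   `channel` (default `"gv_max"`, falling back to the HU channel if gray
#'   values are absent).
#' @param force_series Tibble from [trace_to_displacement()] (columns `x_mm`,
#'   `force_N`).
#' @param cfg An [insertion_config()] used for the intensity profile.
#' @param cfg_force Optional [insertion_config()] applied directly to the raw
#'   force samples. By default (`NULL`) the force onset is found in two
#'   stages: a coarse onset on block means (one block per half profile step,
#'   which suppresses the gauge's autocorrelated noise), then sub-sample
#'   refinement at the raw threshold crossing nearest the coarse onset.
#' @param channel Profile channel: one of `"gv_max"`, `"gv_mean"`, `"gv_min"`,
#'   `"hu_max"`, `"hu_mean"`, `"hu_min"`.
#' @param min_overlap Minimum number of aligned in-bone pairs (default 10).
#' @return An `aligned_pair`: tibble with columns `s_mm`, `intensity_norm`,
#'   `force_norm`; attributes `shift_mm`, `n`, `meta`, `length_mm`, `channel`.
#' @export
align_pair <- function(profile, force_series, cfg = insertion_config(),
                       cfg_force = NULL, channel = "gv_max",
                       min_overlap = 10) {
  if (!channel %in% names(profile)) {
    fallback <- sub("^gv_", "hu_", channel)
    if (!fallback %in% names(profile))
      rlang::abort(sprintf("profile has no channel '%s'", channel))
    channel <- fallback
  }
  s <- profile$s_mm
  intensity <- profile[[channel]]
  onset_i <- detect_insertion(s, intensity, cfg)
  ds_prof <- if (length(s) > 1) s[2] - s[1] else 0.1
  onset_f <- if (is.null(cfg_force))
    detect_force_onset(force_series$x_mm, force_series$force_N, cfg, ds_prof)
  else detect_insertion(force_series$x_mm, force_series$force_N, cfg_force)
  shift <- onset_f - onset_i

  in_range <- s + shift >= min(force_series$x_mm) - 1e-9 &
    s + shift <= max(force_series$x_mm) + 1e-9
  in_bone <- s >= onset_i - 1e-9
  keep <- in_range & in_bone
  if (sum(keep) < min_overlap)
    rlang::abort(sprintf("aligned overlap of %d samples is below the minimum of %d",
                         sum(keep), min_overlap))
  s_keep <- s[keep]
  f_keep <- stats::approx(force_series$x_mm, force_series$force_N,
                          xout = s_keep + shift, rule = 2,
                          ties = "ordered")$y
  out <- tibble::tibble(s_mm = s_keep,
                        intensity_norm = normalize_minmax(intensity[keep]),
                        force_norm = normalize_minmax(f_keep))
  attr(out, "shift_mm") <- shift
  attr(out, "n") <- nrow(out)
  attr(out, "meta") <- attr(profile, "meta")
  p <- attr(profile, "path")
  attr(out, "length_mm") <- if (!is.null(p)) path_length(p) else
    max(s_keep) - min(s_keep)
  attr(out, "channel") <- channel
  class(out) <- c("aligned_pair", class(out))
  out
}
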