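#' Tidy a force-density correlation
#'
#' @param x A `force_density_cor` from [correlate_pair()].
#' @param ... Unused.
#' @return One-row tibble with the correlation estimates, class and labels.
#' @export
tidy.force_density_cor <- function(x, ...) {
  m <- x$meta
  result_row(x, "specimen",
             if (is.null(m)) NA_character_ else m$individual,
             if (is.null(m)) NA_character_ else m$region,
             if (is.null(m)) NA_character_ else m$level)
}

#' Glance at a force-density correlation
#'
#' @param x A `force_density_cor`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `r_spearman`, `p`, `R2`, `significant`.
#' @export
glance.force_density_cor <- function(x, ...) {
  tibble::tibble(n = x$n, r_spearman = x$r_spearman, p = x$p, R2 = x$R2,
                 significant = x$significant)
}

#' Plot a density profile
#'
#' Arc position against the profile channels (one line per channel).
#'
#' @param object A `density_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, ...) {
  chans <- grep("^(hu|gv)_", names(object), value = TRUE)
  df <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(chans),
                            names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mm, y = .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc position along canal [mm]", y = "intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an aligned intensity/force pair
#'
#' Normalized intensity and force against arc position — the standard visual
#' check that the insertion-point alignment worked.
#'
#' @param object An `aligned_pair`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aligned_pair <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("intensity_norm", "force_norm"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mm, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(intensity_norm = "#2166ac", force_norm = "#b2182b"),
      labels = c(intensity_norm = "intensity (normalized)",
                 force_norm = "force (normalized)")) +
    ggplot2::labs(x = "arc position along canal [mm]", y = "normalized value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a grouped correlation table
#'
#' Per-specimen Spearman coefficients coloured by strength class, faceted by
#' individual.
#'
#' @param results Tibble from [grouped_correlations()].
#' @return A ggplot.
#' @export
plot_correlation_results <- function(results) {
  df <- dplyr::filter(results, .data$group_type == "specimen")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$r_spearman,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~individual, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Spearman r", fill = "strength") +
    ggplot2::theme_minimal()
}
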