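#' Plot the permutation null distribution
#'
#' Histogram of the null overlap-count statistics with the observed value
#' marked; an observed count far in the right tail is the visual counterpart
#' of a small empirical p-value.
#'
#' @param object A `coloc_permtest` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_permtest
#' @export
autoplot.coloc_permtest <- function(object, ...) {
  df <- tibble(null_statistic = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("null %s per randomization", object$statistic),
      y = "randomizations",
      title = sprintf("Observed %d vs %d randomizations (p = %.4g)",
                      object$observed, object$n_perm, object$p_add_one)
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed versus randomized nearest-distance distributions
#'
#' Density overlay of the observed nearest-peak distances and the pooled
#' distances after randomizing the reference set; a much narrower observed
#' distribution centered on zero indicates spatial attraction.
#'
#' @param object A `coloc_narrowness` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_narrowness
#' @export
autoplot.coloc_narrowness <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(distance = object$observed_distances, which = "observed"),
    tibble(distance = object$null_distances, which = "randomized")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, colour = .data$which)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = "signed distance to nearest reference peak (bp)", y = "density",
      title = sprintf("IQR ratio %.3g, KS %.3f",
                      object$iqr_ratio, object$ks_statistic),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
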