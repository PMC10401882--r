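#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_line
#'   geom_hline geom_smooth labs theme_minimal scale_color_viridis_d
#' @export
ggplot2::autoplot

#' Plot a 2-D embedding colored by a covariate
#'
#' @param object An [embed_and_score()] result.
#' @param color Covariate to color by: `"site"`, `"sex"`, `"diagnosis"`
#'   or `"age"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.embedding_result <- function(object, color = "site", ...) {
  df <- object$coordinates
  df$.color <- if (color %in% c("sex", "diagnosis")) factor(df[[color]]) else df[[color]]
  p <- ggplot(df, aes(x = .data$dim1, y = .data$dim2, color = .data$.color)) +
    geom_point(alpha = 0.8, size = 1.5) +
    labs(
      x = "t-SNE 1", y = "t-SNE 2", color = color,
      title = sprintf("Embedding (silhouette[site] = %.2f)", object$silhouette["site"])
    ) +
    theme_minimal()
  if (color != "age") p <- p + scale_color_viridis_d()
  p
}

#' Plot a mass-univariate result as -log10 p over features
#'
#' @param object A [site_effect_test()] / [signal_association_test()]
#'   result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mass_univariate_result <- function(object, ...) {
  m <- nrow(object)
  alpha <- attr(object, "alpha")
  ggplot(tibble::as_tibble(object), aes(
    x = .data$feature, y = -log10(pmax(.data$p_value, 1e-300)),
    color = .data$significant
  )) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = -log10(alpha / m), linetype = "dashed") +
    labs(
      x = "feature", y = expression(-log[10](p)),
      title = sprintf(
        "%s effect: %d / %d features significant (FWE %s, alpha %.2f)",
        attr(object, "factor"), sum(object$significant), m,
        attr(object, "fwe"), alpha
      )
    ) +
    theme_minimal()
}

#' Plot the median-ROI summary against age
#'
#' @param x A [median_roi_correlation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_median_age <- function(x, ...) {
  ggplot(x$summary, aes(x = .data$age, y = .data$value, color = .data$site)) +
    geom_point(alpha = 0.8) +
    geom_smooth(aes(group = 1),
      method = "lm", formula = y ~ x,
      se = FALSE, color = "black", linewidth = 0.5
    ) +
    labs(
      x = "age (years)", y = "whole-brain median",
      title = sprintf("Median summary vs age: r = %.4f", x$r)
    ) +
    theme_minimal() +
    scale_color_viridis_d()
}

#' @importFrom rlang .data
NULL
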