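#' Observed vs simulated kinetic curves for one condition
#'
#' @param fit A `de_fit` from [fit_de()].
#' @param title Optional plot title.
#' @return A ggplot object (points = observations, line = model curve).
#' @export
plot_kinetics_fit <- function(fit, title = NULL) {
  df <- fit$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "time (min)", y = "yield (mg GAE / g)",
                  title = title,
                  subtitle = sprintf("rate %.3g /min, RMSE %.3g mg/g, R² %.3f",
                                     fit$rate_per_min, fit$rmse, fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the intra-particle concentration field
#'
#' Renders Cs(xi, t) over the radial coordinate and time, the numerical
#' analogue of spatial concentration-distribution maps.
#'
#' @param profile An `extraction_profile`.
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(profile) {
  df <- profile_to_df(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$xi,
                                   fill = .data$Cs_g_per_cm3)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Cs (g/cm³)") +
    ggplot2::labs(x = "time (min)", y = expression(xi == x / r)) +
    ggplot2::theme_minimal()
}

#' Parity plot of predicted vs observed yields
#'
#' @param predicted,observed Numeric vectors.
#' @param label Subset label (e.g. "training" / "testing").
#' @return A ggplot object with the identity line.
#' @export
plot_parity <- function(predicted, observed, label = "") {
  df <- data.frame(predicted = predicted, observed = observed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "experimental yield (mg/g)",
                  y = "predicted yield (mg/g)", title = label) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Contour plot of a fuzzy-model response surface
#'
#' @param surface Output of [anfis_surface()].
#' @return A ggplot object (filled contours over the two free inputs).
#' @export
plot_surface <- function(surface) {
  df <- surface$df
  names(df)[1:2] <- c("v1", "v2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v1, y = .data$v2,
                                   z = .data$yield_mg_per_g)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = surface$vars[1], y = surface$vars[2],
                  fill = "yield (mg/g)") +
    ggplot2::theme_minimal()
}

#' Stacked-bar chart of category mass proportions per condition
#'
#' @param summary Output of [category_summary()].
#' @return A ggplot object.
#' @export
plot_category_proportions <- function(summary) {
  pr <- summary$proportions
  df <- data.frame(category = rep(rownames(pr), ncol(pr)),
                   condition = rep(colnames(pr), each = nrow(pr)),
                   proportion = as.vector(pr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$proportion,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of quantified mass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' PCA biplot with condition grouping
#'
#' Scores are grouped (colour + 95% normal ellipse, drawn when a group has
#' at least 4 samples) by the condition attribute carried through
#' [expand_replicates()]; loadings are overlaid as scaled arrows. The
#' ellipses are descriptive only.
#'
#' @param pca A `pca_result`.
#' @param components Two component indices (default 1:2).
#' @return A ggplot object.
#' @export
plot_pca_biplot <- function(pca, components = c(1, 2)) {
  sc <- as.data.frame(pca$scores[, components, drop = FALSE])
  names(sc) <- c("PCa", "PCb")
  sc$condition <- pca$condition %||% "sample"
  ld <- as.data.frame(pca$loadings[, components, drop = FALSE])
  names(ld) <- c("PCa", "PCb")
  ld$compound <- rownames(pca$loadings)
  scale_arrows <- 0.8 * max(abs(as.matrix(sc[, 1:2]))) /
    max(abs(as.matrix(ld[, 1:2])))
  lab <- sprintf("PC%d (%.1f%%)", components,
                 pca$explained_pct[components])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PCa, y = .data$PCb,
                                        colour = .data$condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PCa * scale_arrows,
                   yend = .data$PCb * scale_arrows),
      inherit.aes = FALSE, colour = "grey40",
      arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PCa * scale_arrows * 1.07,
                   y = .data$PCb * scale_arrows * 1.07,
                   label = .data$compound),
      inherit.aes = FALSE, colour = "grey30", size = 2.5) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
  if (min(table(sc$condition)) >= 4) {
    p <- p + ggplot2::stat_ellipse(level = 0.95)
  }
  p
}
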