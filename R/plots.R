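#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a link-removal screen
#'
#' Relative expression change per (removal, gene), affected cells
#' outlined.
#'
#' @param object A `limbnet_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot limbnet_screen
#' @export
autoplot.limbnet_screen <- function(object, ...) {
  d <- tidy(object)
  d$removal <- paste(d$removed_source, "→", d$removed_target)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$removal)) +
    ggplot2::geom_tile(ggplot2::aes(fill = pmin(.data$rel_change, 1)),
                       colour = "grey80") +
    ggplot2::geom_point(data = d[d$flagged, ], shape = 8, size = 1.5) +
    ggplot2::scale_fill_viridis_c(name = "relative\nchange",
                                  limits = c(0, 1)) +
    ggplot2::labs(title = paste(object$stage, "link-removal screen"),
                  subtitle = paste0(object$total_affected, " of ",
                                    object$total_cells,
                                    " readouts affected"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a gene impact/sensitivity space
#'
#' Works for both the simulation space ([gene_space()]) and the
#' sensitivity space ([sensitivity_space()]); quadrant boundaries drawn
#' at half the axis maxima.
#'
#' @param space Tibble with `gene`, `impact`, `sensitivity`, `quadrant`.
#' @param axis_max Optional `(sensitivity, impact)` axis maxima.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_gene_space <- function(space, axis_max = NULL, title = NULL) {
  if (is.null(axis_max)) {
    axis_max <- c(max(space$sensitivity), max(space$impact))
  }
  ggplot2::ggplot(space, ggplot2::aes(x = .data$sensitivity,
                                      y = .data$impact)) +
    ggplot2::geom_vline(xintercept = axis_max[1] / 2,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = axis_max[2] / 2,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene),
                       vjust = -0.8, size = 3) +
    ggplot2::expand_limits(x = c(0, axis_max[1]), y = c(0, axis_max[2])) +
    ggplot2::labs(x = "sensitivity to perturbation of others",
                  y = "impact on others when perturbed", title = title) +
    ggplot2::theme_minimal()
}

#' Conservation-by-intensity plot for a subsampling analysis
#'
#' Mean subset conservation per stage with 95% intervals across
#' subsampling intensities; intensities with a significant ES/LS
#' difference are starred.
#'
#' @param object A `limbnet_subsample`.
#' @param alpha Significance level for the stars.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot limbnet_subsample
#' @export
autoplot.limbnet_subsample <- function(object, alpha = 0.05, ...) {
  s <- object$summary
  d <- dplyr::bind_rows(
    tibble::tibble(intensity = s$intensity, stage = "ES",
                   mean = s$es_mean, lo = s$es_lo, hi = s$es_hi),
    tibble::tibble(intensity = s$intensity, stage = "LS",
                   mean = s$ls_mean, lo = s$ls_lo, hi = s$ls_hi)
  )
  stars <- s[!is.na(s$p_value) & s$p_value < alpha, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity,
                                       y = .data$mean,
                                       colour = .data$stage)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi),
                             position = ggplot2::position_dodge(0.02)) +
    ggplot2::labs(x = "subsampling intensity",
                  y = "mean pairwise Spearman conservation",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stars) > 0) {
    p <- p + ggplot2::annotate(
      "text", x = stars$intensity,
      y = max(d$hi) + 0.01 * diff(range(d$mean)), label = "*")
  }
  p
}

#' Histogram of bootstrap correlation replicates
#'
#' @param object A `limbnet_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot limbnet_bootstrap
#' @export
autoplot.limbnet_bootstrap <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed_r,
                        colour = "red") +
    ggplot2::labs(x = "bootstrap Pearson R", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Replicate CoV plot by gene and stage group
#'
#' @param cov_table Output of [stage_cov_summaries()].
#' @return A ggplot object.
#' @export
plot_cov_by_stage <- function(cov_table) {
  ggplot2::ggplot(cov_table,
                  ggplot2::aes(x = .data$gene, y = .data$cov,
                               colour = .data$group)) +
    ggplot2::geom_point(position =
                          ggplot2::position_dodge(width = 0.4)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.35,
                          position =
                            ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "replicate CoV", colour = NULL) +
    ggplot2::theme_minimal()
}
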