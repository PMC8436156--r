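#' Plot per-species viral load change across diets
#'
#' Jittered points of the log2 load change per species, faceted by diet —
#' the standard at-a-glance view of between-species variation in
#' susceptibility.
#'
#' @param table A trait table.
#' @return A ggplot object.
#' @export
plot_load_change <- function(table) {
  d <- dplyr::filter(table, .data$trait_class == "viral_load")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~diet, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Change in RNA viral load (log2)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a posterior summary
#'
#' Point-interval plot (posterior mean with the 95% HPD) of one statistic
#' from a [summarize_pmm()] table; correlations are grouped the way they
#' are reported.
#'
#' @param object A `pmm_summary` tibble.
#' @param statistic Which statistic to plot (default `"correlation"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmm_summary <- function(object, statistic = "correlation", ...) {
  d <- dplyr::filter(object, .data$statistic == !!statistic)
  if (!nrow(d)) abort(paste0("no rows with statistic ", statistic))
  d$label <- ifelse(
    is.na(d$trait_class2),
    paste(d$trait_class, d$diet),
    paste0(d$trait_class, " ", d$diet, " ~ ", d$trait_class2, " ", d$diet2)
  )
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$mean, y = .data$label)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$hpd_lower, xmax = .data$hpd_upper),
      height = 0.2
    ) +
    ggplot2::labs(x = paste0(statistic, " (posterior mean, 95% HPD)"),
                  y = NULL) +
    ggplot2::theme_bw()
  if (statistic == "correlation" && !all(is.na(d$group))) {
    p <- p + ggplot2::facet_grid(group ~ ., scales = "free_y", space = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
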