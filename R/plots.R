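#' Plot a metagene methylation profile
#'
#' @param profile Tibble from [metagene_profile()].
#' @param flank_bins,body_bins Bin counts used to build the profile.
#' @return A ggplot.
#' @export
plot_metagene_profile <- function(profile, flank_bins = 20,
                                  body_bins = 60) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$mean_ml,
                               colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(flank_bins + 0.5,
                                       flank_bins + body_bins + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, flank_bins + 0.5, flank_bins + body_bins + 0.5,
                 2 * flank_bins + body_bins),
      labels = c("-flank", "TSS", "TES", "+flank")
    ) +
    ggplot2::labs(x = NULL, y = "mean methylation level",
                  colour = "context") +
    ggplot2::theme_minimal()
}

#' Plot methylation levels per functional element class
#'
#' @param features Tibble from [feature_levels()], optionally with a
#'   `group` column to dodge two groups side by side.
#' @return A ggplot.
#' @export
plot_feature_levels <- function(features) {
  aes <- if ("group" %in% names(features)) {
    ggplot2::aes(x = .data$class, y = .data$mean_ml, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$class, y = .data$mean_ml)
  }
  ggplot2::ggplot(features, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = "functional element", y = "mean methylation level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-chromosome methylation levels
#'
#' @param levels Tibble from [chromosome_levels()], optionally with a
#'   `group` column.
#' @return A ggplot.
#' @export
plot_chromosome_levels <- function(levels) {
  aes <- if ("group" %in% names(levels)) {
    ggplot2::aes(x = .data$chrom, y = .data$mean_ml, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$chrom, y = .data$mean_ml)
  }
  ggplot2::ggplot(levels, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = "chromosome", y = "mean methylation level") +
    ggplot2::theme_minimal()
}

#' Boxplot of DMR methylation levels per group
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @return A ggplot.
#' @export
plot_dmr_levels <- function(dmrs) {
  long <- tidyr::pivot_longer(dmrs, c("ml_g1", "ml_g2"),
                              names_to = "group", values_to = "ml")
  long$group <- sub("^ml_", "", long$group)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$ml,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "group", y = "DMR methylation level") +
    ggplot2::theme_minimal()
}

#' Autoplot a DMR scan: per-group DMR level boxplots
#'
#' @param object A `dmr_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.dmr_scan <- function(object, ...) {
  plot_dmr_levels(object$dmrs)
}

#' @export
ggplot2::autoplot
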