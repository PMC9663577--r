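#' Plot a TFBS expansion profile
#'
#' Density of pairwise K2P distances with detected modes marked; multiple
#' modes indicate repeated expansion waves.
#'
#' @param object An `expansion_profile` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expansion_profile <- function(object, ...) {
  d <- filter(object$distances, !is.na(.data$distance))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_density(bw = object$bandwidth, fill = "grey80") +
    ggplot2::labs(x = "K2P distance (substitutions/site)", y = "density",
                  title = sprintf("TFBS pairwise distances (n = %d sequences)",
                                  object$n_sequences)) +
    ggplot2::theme_minimal()
  if (nrow(object$modes) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$modes$location,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot cross-lineage TE distance distributions
#'
#' One density per lineage pair; within-lineage distributions dashed. A
#' shared between-lineage mode indicates an expansion predating the
#' lineage split.
#'
#' @param object A `lineage_distance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lineage_distance <- function(object, ...) {
  d <- mutate(object$distances,
              pair = paste(.data$lineage_1, .data$lineage_2, sep = "-"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, colour = .data$pair,
                                  linetype = .data$within)) +
    ggplot2::geom_density() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   name = "within lineage") +
    ggplot2::labs(x = "merged-LTR K2P distance", y = "density") +
    ggplot2::theme_minimal()
}

#' Heatmap of TF binding correlations
#'
#' @param object A `tf_cor` object (see [tf_binding_correlation()]); TFs
#'   are shown in clustering order.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_cor <- function(object, ...) {
  d <- tidy.tf_cor(object)
  d <- mutate(d, tf_1 = factor(.data$tf_1, levels = object$order),
              tf_2 = factor(.data$tf_2, levels = object$order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf_1, y = .data$tf_2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar plot of triad balance-pattern frequencies
#'
#' @param patterns Output of [classify_patterns()].
#' @return A ggplot of pattern counts per TF (filtered triads excluded).
#' @export
plot_pattern_frequencies <- function(patterns) {
  d <- filter(patterns, !is.na(.data$pattern))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pattern)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~tf_id) +
    ggplot2::labs(x = "balance pattern", y = "triads") +
    ggplot2::theme_minimal()
}

#' Histogram of TE insertion ages
#'
#' @param ages Output of [te_insertion_age()].
#' @param bins Number of histogram bins.
#' @return A ggplot faceted by subfamily, ages in million years.
#' @export
plot_te_ages <- function(ages, bins = 30) {
  d <- filter(ages, !.data$saturated)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_years / 1e6)) +
    ggplot2::geom_histogram(bins = bins, fill = "darkolivegreen4") +
    ggplot2::facet_wrap(~subfamily, scales = "free_y") +
    ggplot2::labs(x = "insertion age (Myr)", y = "elements") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
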