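# ggplot2 views of the package's result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.ld_curve <- function(object, threshold = 0.2, ...) {
  ggplot2::ggplot(object[!is.na(object$mean_r2), ],
                  ggplot2::aes(x = .data$mid / 1000, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "pair distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.window_stats <- function(object, ...) {
  avg <- attr(object, "genome_avg")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$value)) +
    ggplot2::geom_line(colour = "black", linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = attr(object, "stat") %||% "value") +
    ggplot2::theme_minimal()
  if (!is.null(avg))
    p <- p + ggplot2::geom_hline(yintercept = avg, linetype = "dashed",
                                 colour = "red")
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.sfs <- function(object, ...) {
  df <- tibble::tibble(class = seq_along(object$counts),
                       proportion = object$proportions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = if (object$folded) "minor-allele count"
                  else "derived-allele count",
                  y = "proportion of segregating sites",
                  title = "site-frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a metagene methylation profile
#'
#' @param profile Output of [metagene_profile()] (optionally several,
#'   bound with a `context` column).
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  nb <- max(profile$bin)
  body_lo <- min(profile$bin[profile$zone == "body"]) - 0.5
  body_hi <- max(profile$bin[profile$zone == "body"]) + 0.5
  aes <- if ("context" %in% names(profile))
    ggplot2::aes(x = .data$bin, y = .data$wml, colour = .data$context)
  else ggplot2::aes(x = .data$bin, y = .data$wml)
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(body_lo, body_hi),
                        linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = c(1, body_lo + 0.5, body_hi - 0.5,
                                           nb),
                                labels = c("-2kb", "start", "end", "+2kb")) +
    ggplot2::labs(x = NULL, y = "weighted methylation level") +
    ggplot2::theme_minimal()
}

#' Population summary panel (diversity, LD, efficacy of selection, H)
#'
#' Bar panels of per-population pi, LD-decay distance, piN/piS and median
#' heterozygosity, mirroring the classic four-statistic comparison.
#'
#' @param summary_tbl Tibble with `population` and any of `pi`,
#'   `ld_decay_kb`, `pin_pis`, `median_het`.
#' @return A ggplot.
#' @export
plot_population_summary <- function(summary_tbl) {
  long <- tidyr::pivot_longer(summary_tbl, -"population",
                              names_to = "statistic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population, y = .data$value,
                                     fill = .data$population)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
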