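#' Volcano plot of differential expression
#'
#' log2 fold change against -log10 raw P, with the screening thresholds
#' drawn and called probes highlighted.
#'
#' @param de table from [moderated_t_test()].
#' @param fc_threshold,p_threshold thresholds to draw (defaults 1.5, 0.05).
#' @return a ggplot object.
#' @export
plot_volcano <- function(de, fc_threshold = 1.5, p_threshold = 0.05) {
  de$status <- ifelse(!de$is_de, "not DE",
                      ifelse(de$log2fc > 0, "up", "down"))
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2e86c1",
                                            `not DE` = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = expression(-log[10] ~ P), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of enrichment results
#'
#' -log10 P of the significant gene sets, largest first.
#'
#' @param res table from [ora()].
#' @param top_n sets to show (default 20).
#' @return a ggplot object.
#' @export
plot_enrichment <- function(res, top_n = 20) {
  res <- utils::head(res[res$significant, , drop = FALSE], top_n)
  res$set_id <- factor(res$set_id, levels = rev(res$set_id))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$set_id,
                                    y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "#2e86c1") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ P)) +
    ggplot2::theme_minimal()
}

#' Grouped bars of qPCR relative expression with significance stars
#'
#' Mean fold per gene and group with SE bars; stars mark P < 0.05 (*) and
#' P < 0.01 (**) from the per-gene group comparison.
#'
#' @param rel table from [delta_delta_ct()].
#' @param comparison table from [group_compare()].
#' @return a ggplot object.
#' @export
plot_qpcr <- function(rel, comparison) {
  agg <- stats::aggregate(fold ~ gene_id + group, rel,
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v))))
  agg <- data.frame(agg[1:2], agg$fold)
  stars <- data.frame(
    gene_id = comparison$gene_id,
    label = ifelse(comparison$p_value < 0.01, "**",
                   ifelse(comparison$p_value < 0.05, "*", "")),
    y = vapply(comparison$gene_id, function(g)
      max(agg$mean[agg$gene_id == g] + agg$se[agg$gene_id == g]) * 1.05,
      numeric(1L)))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$gene_id, y = .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.2) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = .data$gene_id, y = .data$y,
                                    label = .data$label),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "relative expression (fold)", fill = NULL) +
    ggplot2::theme_minimal()
}
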