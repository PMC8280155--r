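#' Plot a candidate ranking
#'
#' Lollipop chart of composite (or classifier) scores, best candidates on
#' top; unqualified compounds (support below the cell-line rule) are greyed
#' out at the bottom.
#'
#' @param object A `candidate_ranking` from [rank_candidates()].
#' @param top_n How many compounds to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_ranking <- function(object, top_n = 20L, ...) {
  df <- head(as_tibble(object), top_n)
  df$compound_id <- factor(df$compound_id, levels = rev(df$compound_id))
  df$score_plot <- ifelse(is.finite(df$score), df$score, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score_plot, y = .data$compound_id,
                                   colour = .data$qualified)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score_plot,
                                       yend = .data$compound_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey60")) +
    ggplot2::labs(x = "screening score", y = NULL, colour = "qualified") +
    ggplot2::theme_minimal()
}

#' Heatmap of a panel consensus table
#'
#' @param object A `panel_table` from [panel_consensus_table()].
#' @param ... Unused.
#' @return A ggplot object: genes by perturbations, tile fill = consensus z.
#' @export
autoplot.panel_table <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"gene",
                              names_to = "perturbation", values_to = "z")
  long$gene <- factor(long$gene, levels = rev(object$gene))
  long$perturbation <- factor(long$perturbation,
                              levels = setdiff(names(object), "gene"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$perturbation, y = .data$gene,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$z)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of normalized enrichment scores
#'
#' @param object A `gsea_result` from [gsea_preranked()].
#' @param alpha FDR cutoff colouring significant sets (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsea_result <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$set_name <- factor(df$set_name, levels = df$set_name[order(df$nes)])
  df$significant <- df$fdr_q < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set_name,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey70"),
                               labels = c(`TRUE` = sprintf("FDR < %.2g", alpha),
                                          `FALSE` = "n.s.")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Running-sum enrichment plot for one gene set
#'
#' The classical GSEA mountain plot: the weighted running sum along the
#' ranked list with hit positions marked in the rug.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of member gene ids (or one `gene_sets`
#'   row).
#' @param weight_exponent Passed to [enrichment_score()].
#' @return A ggplot object.
#' @export
plot_running_sum <- function(ranked, gene_set, weight_exponent = 1) {
  res <- enrichment_score(ranked, gene_set, weight_exponent)
  members <- extract_members(gene_set)
  df <- tibble(position = seq_len(nrow(ranked)), running = res$running_sum)
  hits <- tibble(position = which(ranked$gene_id %in% members))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$position),
                      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(x = "rank in list", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", res$es)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-cell colocalization coefficients by group
#'
#' @param coefficients A data frame with columns `group` and a coefficient
#'   column (default `m1`).
#' @param coefficient Which column to plot.
#' @return A ggplot object with group means overlaid.
#' @export
plot_coloc_groups <- function(coefficients, coefficient = "m1") {
  ggplot2::ggplot(coefficients,
                  ggplot2::aes(x = .data$group, y = .data[[coefficient]])) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "#b2182b") +
    ggplot2::labs(x = NULL, y = coefficient) +
    ggplot2::theme_minimal()
}
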