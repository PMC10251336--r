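#' Fold-change scatter with regression line and outlier classes
#'
#' The classic classification view: per-gene SoF vs Ctrl log2 fold
#' changes, the significance-gated regression line, and the MCD outliers
#' colored by the side of the line they fall on.
#'
#' @param classification a [classify_gene_sets()] result.
#' @return a ggplot object.
#' @export
plot_foldchange_pairs <- function(classification) {
  stopifnot(inherits(classification, "sofdex_classification"))
  pairs <- classification$pairs |>
    left_join(classification$labels, by = "gene_id") |>
    filter(is.finite(.data$log2FC_SoF), is.finite(.data$log2FC_Ctrl))
  line <- classification$line
  ggplot2::ggplot(pairs, ggplot2::aes(
    x = .data$log2FC_SoF, y = .data$log2FC_Ctrl, color = .data$class
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(
      slope = line$slope, intercept = line$intercept, linetype = 2
    ) +
    ggplot2::scale_color_manual(values = c(
      background = "grey70", sof_dexdep = "#d95f02", sof_3h_rep = "#7570b3",
      sof_dexind = "#1b9e77", sof_const_rep = "#e7298a"
    )) +
    ggplot2::labs(
      x = "log2FC (SoF, dex vs vehicle)", y = "log2FC (Ctrl, dex vs vehicle)",
      color = "gene set"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sofdex_classification <- function(object, ...) {
  plot_foldchange_pairs(object)
}

#' Relative-distance histogram against the uniform null
#'
#' @param reldist a [relative_distance()] result.
#' @return a ggplot object; the dashed line is the Uniform[0, 0.5]
#'   density expected under no co-occurrence.
#' @export
plot_relative_distance <- function(reldist) {
  h <- reldist$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$fraction)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1], fill = "#1b9e77") +
    ggplot2::geom_hline(yintercept = 1 / nrow(h), linetype = 2) +
    ggplot2::labs(x = "relative distance (TSS to flanking ChIP-peak midpoints)",
      y = "fraction of TSSs") +
    ggplot2::theme_minimal()
}

#' Gene-set abundance z-scores over the treatment time course
#'
#' @param zscores a [zscore_abundance()] tibble.
#' @return a ggplot object (boxplots per time, colored by genotype).
#' @export
plot_zscore_abundance <- function(zscores) {
  ggplot2::ggplot(zscores, ggplot2::aes(
    x = factor(.data$time), y = .data$zscore, fill = .data$genotype
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "dexamethasone treatment (h)", y = "abundance z-score") +
    ggplot2::theme_minimal()
}

#' Enriched-region track along chromosomes
#'
#' @param regions a [positional_scan()] tibble.
#' @return a ggplot object with one horizontal segment per region,
#'   annotated by adjusted p-value.
#' @export
plot_enriched_regions <- function(regions) {
  ggplot2::ggplot(regions, ggplot2::aes(
    x = .data$start / 1e6, xend = .data$end / 1e6,
    y = .data$chrom, yend = .data$chrom
  )) +
    ggplot2::geom_segment(linewidth = 3, color = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2e6,
      label = sprintf("padj = %.2g", .data$padj)
    ), vjust = -1, size = 3) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
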