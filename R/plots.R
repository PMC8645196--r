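# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_vline geom_density labs
#'   theme_minimal facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot sample PCA coloured by karyotype
#'
#' @param object An `invexpr_pca` object.
#' @param colour,shape Metadata columns mapped to colour and shape (defaults
#'   `karyotype`, `sex` when present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot invexpr_pca
#' @export
autoplot.invexpr_pca <- function(object, colour = "karyotype", shape = "sex", ...) {
  sc <- object$scores
  has_col <- colour %in% names(sc)
  has_shape <- shape %in% names(sc)
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2))
  pts <- if (has_col && has_shape) {
    geom_point(aes(colour = .data[[colour]], shape = .data[[shape]]), size = 2.5)
  } else if (has_col) {
    geom_point(aes(colour = .data[[colour]]), size = 2.5)
  } else geom_point(size = 2.5)
  p + pts +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    theme_minimal()
}

#' Manhattan-style plot of a contrast along the genome
#'
#' Each point is a transcript at its genomic position; y is the log2 fold
#' change (negative = higher in the second level, e.g. ββ); dashed lines
#' mark the inversion breakpoints.
#'
#' @param results Contrast result tibble.
#' @param map Transcript map.
#' @param layout A [genome_layout()].
#' @return A ggplot faceted by linkage group.
#' @export
plot_manhattan <- function(results, map, layout) {
  d <- dplyr::inner_join(results, map, by = "transcript_id")
  d <- d[d$region %in% layout$linkage_groups$lg, , drop = FALSE]
  bp <- tibble(region = layout$inversion$lg,
               pos = unname(layout$breakpoints) / 1e6)
  ggplot(d, aes(x = .data$start / 1e6, y = .data$log2fc,
                colour = -log10(pmax(.data$padj, 1e-20)))) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(data = bp, aes(xintercept = .data$pos),
               linetype = "dashed", colour = "magenta") +
    facet_wrap(~region, nrow = 1, scales = "free_x") +
    labs(x = "position (Mb)", y = "log2 fold change",
         colour = expression(-log[10]~adj.~p)) +
    theme_minimal()
}

#' Density of log2 fold changes, genome-wide vs within the inversion
#'
#' @param results Contrast result tibble.
#' @param labels Tibble from [assign_region()].
#' @return A ggplot with one density per set.
#' @export
plot_lfc_density <- function(results, labels) {
  d <- dplyr::left_join(results, labels, by = "transcript_id")
  inv <- d[!is.na(d$region_label) & d$region_label == "inversion", ]
  both <- dplyr::bind_rows(dplyr::mutate(d, set = "genome"),
                           dplyr::mutate(inv, set = "inversion"))
  ggplot(both, aes(x = .data$log2fc, fill = .data$set)) +
    geom_density(alpha = 0.5) +
    ggplot2::scale_fill_manual(values = c(genome = "grey60", inversion = "magenta")) +
    labs(x = "log2 fold change", y = "density") +
    theme_minimal()
}

#' Per-pool allele fractions for classified ASE transcripts
#'
#' @param calls Tibble from [classify_ase()].
#' @param fractions Tibble from [per_transcript_fractions()].
#' @param cutoff Cutoff drawn as reference lines (default 0.55).
#' @return A ggplot: one column of points per transcript, coloured by call.
#' @export
plot_ase_fractions <- function(calls, fractions, cutoff = 0.55) {
  d <- dplyr::inner_join(fractions,
                         dplyr::select(calls, "transcript_id", "call"),
                         by = "transcript_id")
  d <- d[d$call != "not_significant", , drop = FALSE]
  ggplot(d, aes(x = .data$transcript_id, y = .data$alpha_frac,
                colour = .data$call)) +
    geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(cutoff, 1 - cutoff), linetype = "dashed") +
    labs(x = NULL, y = "α-allele read fraction") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
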