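#' Stacked splicing-stage fractions
#'
#' @param object A `splice_classification` from [classify_sample()].
#' @param ... Unused.
#' @return A ggplot: one stacked bar of category fractions.
#' @exportS3Method ggplot2::autoplot
autoplot.splice_classification <- function(object, ...) {
  s <- filter(object$summary, .data$count > 0)
  ggplot(s, aes(x = "", y = .data$fraction, fill = .data$category)) +
    geom_col(width = 0.6) +
    coord_flip() +
    labs(x = NULL, y = "fraction of classified read pairs",
         fill = "stage",
         title = sprintf("Splicing-stage classification: %s",
                         object$gene_id)) +
    theme_minimal()
}

#' SSI and coverage panels per intron
#'
#' Mirrors the standard three-panel view: exon coverage, SSI5/SSI3 per
#' intron, intron coverage.
#'
#' @param object An `ssi_table` from [splice_site_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ssi_table <- function(object, ...) {
  tbl <- as_tibble(unclass_tbl(object))
  long <- tbl |>
    select("intron", "SSI5", "SSI3", "intron_median") |>
    pivot_longer(-"intron", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = factor(.data$intron), y = .data$value)) +
    geom_col(fill = "grey30") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "intron (transcription order)", y = NULL,
         title = sprintf("Splice-site indices and intron coverage: %s",
                         attr(object, "gene_id") %||% "")) +
    theme_minimal()
}

#' Signed gap-peak track
#'
#' @param object A `gap_peaks` (or consensus) tibble.
#' @param ... Unused.
#' @return A ggplot of signed peak magnitudes along the locus.
#' @exportS3Method ggplot2::autoplot
autoplot.gap_peaks <- function(object, ...) {
  d <- as_tibble(unclass_tbl(object))
  ggplot(d, aes(x = .data$pos, xend = .data$pos,
                y = 0, yend = .data$sign * .data$magnitude)) +
    geom_segment(linewidth = 0.8) +
    geom_hline(yintercept = 0, colour = "grey60") +
    labs(x = "genomic position", y = "signed peak magnitude",
         title = "Inverted-coverage derivative peaks") +
    theme_minimal()
}

#' Donor-by-acceptor junction heatmap
#'
#' @param x A `junction_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map (donor columns, acceptor rows).
#' @export
plot_junction_matrix <- function(x, ...) {
  d <- as_tibble(unclass_tbl(x))
  ggplot(d, aes(x = factor(.data$donor), y = factor(.data$acceptor),
                fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), colour = "white", size = 3) +
    labs(x = "donor splice site", y = "acceptor splice site",
         fill = "reads",
         title = "Split-read support per discovered junction") +
    theme_minimal()
}
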