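#' @rdname splice_classification_tidiers
#' @title Broom-style tidiers for classification results
#' @description `tidy()` returns the per-category summary; `glance()` a
#'   one-row overview with category fractions.
#' @param x A `splice_classification` from [classify_sample()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.splice_classification <- function(x, ...) {
  x$summary
}

#' @rdname splice_classification_tidiers
#' @exportS3Method generics::glance
glance.splice_classification <- function(x, ...) {
  s <- x$summary
  fr <- setNames(as.list(s$fraction), paste0(s$category, "_fraction"))
  bind_cols(tibble(gene_id = x$gene_id, n_pairs = x$n_pairs,
                   n_unpaired = x$n_unpaired),
            as_tibble(fr))
}

#' @rdname ssi_tidiers
#' @title Tidiers for splice-site tables
#' @description `tidy()` strips the class; `glance()` summarises SSI means
#'   and coverage.
#' @param x An `ssi_table` from [splice_site_table()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ssi_table <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname ssi_tidiers
#' @exportS3Method generics::glance
glance.ssi_table <- function(x, ...) {
  tibble(gene_id = attr(x, "gene_id"),
         n_introns = nrow(x),
         mean_SSI5 = mean(x$SSI5, na.rm = TRUE),
         mean_SSI3 = mean(x$SSI3, na.rm = TRUE),
         mean_intron_cov = mean(x$intron_median))
}

#' @rdname nonseq_tidiers
#' @title Tidiers for non-sequential splicing calls
#' @description `tidy()` returns the per-pair call table; `glance()` the
#'   run-level settings plus the coverage-vs-read-evidence correlations.
#' @param x A `nonseq_calls` from [call_nonsequential()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nonseq_calls <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname nonseq_tidiers
#' @exportS3Method generics::glance
glance.nonseq_calls <- function(x, ...) {
  tibble(n_pairs_tested = nrow(x),
         n_called = sum(x$called),
         n_samples = attr(x, "n_samples"),
         min_samples = attr(x, "min_samples"),
         ratio_cutoff = attr(x, "ratio_cutoff"),
         cor_pearson = attr(x, "cor_pearson"),
         cor_spearman = attr(x, "cor_spearman"))
}

# strip a result class but keep the tibble
unclass_tbl <- function(x) {
  class(x) <- class(x)[!class(x) %in%
                         c("ssi_table", "nonseq_calls", "gap_peaks",
                           "junction_matrix")]
  x
}
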