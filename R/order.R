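#' Coverage-based candidates for non-sequential splicing
#'
#' Under sequential 5'->3' splicing an upstream intron is removed earlier,
#' so the downstream neighbour should show the *higher* steady-state
#' coverage. For each adjacent pair (i, i+1) the difference
#' `delta = median_cov(intron_i+1) - median_cov(intron_i)` is computed; a
#' strongly negative delta suggests intron i+1 is removed before intron i.
#' The significance cutoff is the first quartile Q1 (linear-interpolation
#' quantile) of the negative deltas; pairs with `delta <= Q1` are flagged.
#' The inclusive comparison keeps the rule meaningful when few negative
#' deltas exist (with a single negative delta, Q1 equals it and that pair
#' -- the extreme difference the rule is after -- is flagged). The third
#' quartile is available for sensitivity analysis.
#'
#' @param cov Tibble with `intron` and a coverage column (`intron_median` or
#'   `median_cov`), one row per intron of one gene in one sample -- e.g. a
#'   [splice_site_table()] or the intron rows of [median_coverage()].
#' @param quartile `"Q1"` (normative) or `"Q3"`.
#' @return Tibble per adjacent pair: `intron_i`, `intron_j` (= i+1),
#'   `delta`, `cutoff`, `candidate`.
#' @export
#' @examples
#' cov <- tibble::tibble(intron = 1:5,
#'                       intron_median = c(20, 10, 8, 6, 5))
#' coverage_candidates(cov)
coverage_candidates <- function(cov, quartile = c("Q1", "Q3")) {
  quartile <- match.arg(quartile)
  col <- intersect(c("intron_median", "median_cov"), names(cov))[1]
  if (is.na(col)) abort("no intron coverage column found")
  cov <- arrange(as_tibble(cov)[, c("intron", col)], .data$intron)
  m <- cov[[col]]
  n_pairs <- nrow(cov) - 1L
  if (n_pairs < 4) {
    warn(sprintf("only %d adjacent pairs; quartile cutoff is unstable",
                 n_pairs))
  }
  delta <- m[-1] - m[-length(m)]
  neg <- delta[delta < 0]
  cutoff <- if (length(neg) > 0) {
    unname(quantile(neg, if (quartile == "Q1") 0.25 else 0.75, type = 7))
  } else {
    NA_real_
  }
  tibble(intron_i = cov$intron[-nrow(cov)],
         intron_j = cov$intron[-1],
         delta = delta,
         cutoff = cutoff,
         candidate = !is.na(cutoff) & delta <= cutoff)
}

#' Read-based splice-ratio for adjacent intron pairs
#'
#' A read pair with one end inside the upstream intron i and the mate split
#' across the junction over the downstream intron i+1 shows intron i+1 was
#' removed while intron i was still present: evidence for *non-sequential*
#' splicing. The mirror configuration (end split across intron i's
#' junction, mate inside intron i+1) supports sequential splicing. The
#' splice-ratio `seq / (seq + nonseq)` is close to 1 under sequential
#' removal and close to 0 when the downstream intron goes first; `NA` when
#' no informative pairs exist.
#'
#' @param x BAM path, `GAlignments`, or a `splice_classification` from
#'   [classify_sample()] (reusing its labeled pairs avoids re-reading).
#' @param model A [gene_model()].
#' @inheritParams classify_pair
#' @return Tibble per adjacent pair: `intron_i`, `intron_j`, `seq_count`,
#'   `nonseq_count`, `splice_ratio`.
#' @export
splice_ratios <- function(x, model, expected_distance = 650,
                          large_threshold = 650) {
  cls <- if (inherits(x, "splice_classification")) {
    x
  } else {
    classify_sample(x, model, expected_distance, large_threshold)
  }
  pairs <- cls$pairs
  introns <- sort(model$introns$intron)
  n_adj <- length(introns) - 1L

  # int end in intron a, mate ex-ex spanning junction over intron b
  int_jx <- bind_rows(
    pairs |>
      filter(.data$label1 == "int", .data$label2 == "ex-ex") |>
      transmute(a = .data$feat_idx1, jx = .data$jx2),
    pairs |>
      filter(.data$label2 == "int", .data$label1 == "ex-ex") |>
      transmute(a = .data$feat_idx2, jx = .data$jx1)
  ) |>
    unnest("jx")

  count_cfg <- function(int_idx, jx_idx) {
    sum(int_jx$a == int_idx & int_jx$jx == jx_idx)
  }
  res <- tibble(
    intron_i = introns[seq_len(n_adj)],
    intron_j = introns[seq_len(n_adj) + 1L]
  ) |>
    mutate(
      nonseq_count = purrr::map2_int(.data$intron_i, .data$intron_j,
                                     ~ count_cfg(.x, .y)),
      seq_count = purrr::map2_int(.data$intron_j, .data$intron_i,
                                  ~ count_cfg(.x, .y)),
      splice_ratio = ifelse(.data$seq_count + .data$nonseq_count > 0,
                            .data$seq_count /
                              (.data$seq_count + .data$nonseq_count),
                            NA_real_)
    )
  res
}

#' Per-sample evidence table for splicing order
#'
#' Combines [coverage_candidates()] and [splice_ratios()] for one sample.
#'
#' @param x BAM path or `GAlignments`.
#' @param model A [gene_model()].
#' @param quartile Passed to [coverage_candidates()].
#' @inheritParams classify_pair
#' @return Tibble per adjacent pair with `delta`, `cutoff`, `candidate`,
#'   `seq_count`, `nonseq_count`, `splice_ratio`.
#' @export
order_evidence <- function(x, model, quartile = "Q1",
                           expected_distance = 650, large_threshold = 650) {
  gal <- .as_gal(x, model)
  cov <- median_coverage(gal, model) |>
    filter(.data$kind == "intron") |>
    select(intron = "index", "median_cov")
  cand <- coverage_candidates(cov, quartile)
  ratios <- splice_ratios(gal, model, expected_distance, large_threshold)
  left_join(cand, ratios, by = c("intron_i", "intron_j"))
}

#' Call non-sequentially spliced intron pairs across samples
#'
#' A pair (i, i+1) is called non-sequential when it is a coverage candidate
#' in at least `min_samples` RNA samples, the splice-ratio is below
#' `ratio_cutoff` in every supporting sample that has read evidence (the
#' read requirement is waived at zero informative pairs, as in low-coverage
#' whole-transcriptome data), and it is *not* a coverage candidate in the
#' DNA control -- DNA does not splice, so a control candidate indicates
#' mappability or sequencing bias rather than biology.
#'
#' @param evidence Named list of per-sample [order_evidence()] tibbles (RNA
#'   samples).
#' @param control Optional [order_evidence()] tibble from a DNA control.
#' @param min_samples Minimum number of RNA samples in which the pair must
#'   be a coverage candidate.
#' @param ratio_cutoff Splice-ratio threshold (default 0.5).
#' @return Object of class `nonseq_calls`: tibble per adjacent pair with
#'   `n_candidate`, `mean_delta`, `mean_ratio`, `n_ratio_defined`,
#'   `ratio_ok`, `control_candidate`, `called`; the Pearson and Spearman
#'   correlations between the coverage evidence (delta) and the read
#'   evidence (ratio) across pairs are stored in attributes
#'   `cor_pearson`/`cor_spearman` and shown by [glance()].
#' @export
call_nonsequential <- function(evidence, control = NULL,
                               min_samples = length(evidence),
                               ratio_cutoff = 0.5) {
  stopifnot(length(evidence) >= 1)
  if (min_samples > length(evidence)) {
    abort(sprintf("min_samples (%d) exceeds number of RNA samples (%d)",
                  min_samples, length(evidence)),
          class = "splicestage_min_samples")
  }
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    names(evidence) <- paste0("sample", seq_along(evidence))
  }
  all_ev <- purrr::imap(evidence, ~ mutate(.x, sample = .y)) |>
    list_rbind()

  per_pair <- all_ev |>
    group_by(.data$intron_i, .data$intron_j) |>
    summarise(
      n_candidate = sum(.data$candidate),
      mean_delta = mean(.data$delta),
      mean_ratio = mean(.data$splice_ratio, na.rm = TRUE),
      n_ratio_defined = sum(.data$candidate & !is.na(.data$splice_ratio)),
      ratio_ok = all(.data$splice_ratio[.data$candidate] < ratio_cutoff,
                     na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(mean_ratio = ifelse(is.nan(.data$mean_ratio), NA_real_,
                               .data$mean_ratio))

  ctrl <- if (!is.null(control)) {
    select(control, "intron_i", "intron_j", control_candidate = "candidate")
  } else {
    tibble(intron_i = per_pair$intron_i, intron_j = per_pair$intron_j,
           control_candidate = FALSE)
  }
  calls <- per_pair |>
    left_join(ctrl, by = c("intron_i", "intron_j")) |>
    mutate(control_candidate = replace_na(.data$control_candidate, FALSE),
           called = .data$n_candidate >= min_samples &
             .data$ratio_ok & !.data$control_candidate)

  both <- filter(calls, !is.na(.data$mean_ratio))
  cp <- if (nrow(both) >= 3 && stats::sd(both$mean_ratio) > 0 &&
              stats::sd(both$mean_delta) > 0) {
    c(cor(both$mean_delta, both$mean_ratio, method = "pearson"),
      cor(both$mean_delta, both$mean_ratio, method = "spearman"))
  } else {
    c(NA_real_, NA_real_)
  }

  structure(calls, class = c("nonseq_calls", class(calls)),
            cor_pearson = cp[1], cor_spearman = cp[2],
            min_samples = min_samples, ratio_cutoff = ratio_cutoff,
            n_samples = length(evidence))
}
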