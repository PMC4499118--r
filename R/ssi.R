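#' Count junction- and boundary-spanning reads per intron
#'
#' For every intron the table records `ex_ex` (ends split exactly across the
#' annotated exon-exon junction), `ex_int_5` (contiguous blocks crossing the
#' exon/intron boundary at the intron's transcriptional 5' splice site) and
#' `ex_int_3` (same at the 3' splice site). An end counts toward a site only
#' when it spans it by at least `anchor` bases on both sides, and a single
#' end can count toward every distinct site it genuinely spans. Both mates
#' of a pair are counted independently.
#'
#' @param x BAM path or `GAlignments`.
#' @param model A [gene_model()].
#' @param anchor Minimum aligned bases required on each side of a boundary
#'   or junction (default 3); suppresses 1-bp overhang noise.
#' @return Tibble with one row per intron: `intron`, `ex_ex`, `ex_int_5`,
#'   `ex_int_3`.
#' @export
count_boundary_reads <- function(x, model, anchor = 3) {
  gal <- .as_gal(x, model)
  introns <- model$introns
  n <- nrow(introns)

  # boundary positions: p | p+1 with p the last base of the left feature.
  # 5' splice site of intron i sits at the genomic left edge on '+' strands
  # and the right edge on '-' strands.
  left_p <- introns$start - 1L
  right_p <- introns$end
  p5 <- if (model$strand == "+") left_p else right_p
  p3 <- if (model$strand == "+") right_p else left_p

  irl <- .ref_blocks(gal)
  ir <- unlist(irl, use.names = FALSE)
  bs <- start(ir); be <- end(ir)
  cross <- function(p) {
    vapply(p, function(pp) {
      sum(bs <= pp - anchor + 1L & be >= pp + anchor)
    }, integer(1))
  }

  gt <- .gap_table(gal)
  ex_ex <- vapply(seq_len(n), function(i) {
    sum(gt$gap_start == introns$start[i] & gt$gap_end == introns$end[i] &
          gt$left_w >= anchor & gt$right_w >= anchor)
  }, integer(1))

  tibble(intron = introns$intron,
         ex_ex = ex_ex,
         ex_int_5 = cross(p5),
         ex_int_3 = cross(p3)) |>
    arrange(.data$intron)
}

#' Compute the Splice Site Index from boundary/junction counts
#'
#' The SSI at a splice site is the fraction of informative reads that span
#' the spliced junction rather than the unspliced boundary:
#' `SSI = ex_ex / (ex_ex + ex_int)`, computed separately at each intron's
#' 5' site (`SSI5`) and 3' site (`SSI3`). 1 means fully spliced at that
#' site, 0 fully unspliced; `NA` when no informative reads exist. The ratio
#' is scale-invariant: multiplying all counts by a constant leaves it
#' unchanged.
#'
#' @param counts Tibble from [count_boundary_reads()].
#' @return The same tibble with `SSI5` and `SSI3` columns added.
#' @export
#' @examples
#' compute_ssi(tibble::tibble(intron = 1, ex_ex = 3, ex_int_5 = 1,
#'                            ex_int_3 = 0))
compute_ssi <- function(counts) {
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  mutate(counts,
         SSI5 = ratio(.data$ex_ex, .data$ex_ex + .data$ex_int_5),
         SSI3 = ratio(.data$ex_ex, .data$ex_ex + .data$ex_int_3))
}

#' Median per-base coverage of every exon and intron
#'
#' Per-base depth counts aligned blocks only -- CIGAR `N` gaps contribute
#' nothing -- and duplicates are not removed (replicate consistency, not
#' deduplication, is the pipeline's guard against PCR artifacts). The
#' median is taken across the positions of each feature.
#'
#' @param x BAM path or `GAlignments`.
#' @param model A [gene_model()].
#' @return Tibble `kind`, `index`, `start`, `end`, `median_cov`.
#' @export
median_coverage <- function(x, model) {
  gal <- .as_gal(x, model)
  span <- gene_span(model)
  cov <- coverage(gal)
  v <- if (model$chrom %in% names(cov)) as.numeric(cov[[model$chrom]]) else numeric(0)
  if (length(v) < span[2]) v <- c(v, numeric(span[2] - length(v)))
  feature_table(model) |>
    mutate(median_cov = purrr::map2_dbl(.data$start, .data$end,
                                        ~ median(v[.x:.y])))
}

#' Per-intron splice-site table: counts, SSI and flanking coverage
#'
#' One-stop summary combining [count_boundary_reads()], [compute_ssi()] and
#' [median_coverage()]: per intron the junction/boundary counts, SSI5/SSI3,
#' the intron's median coverage and that of its transcriptionally flanking
#' exons.
#'
#' @inheritParams count_boundary_reads
#' @return Object of class `ssi_table`: the per-intron tibble plus an
#'   `exon_coverage` attribute; supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
splice_site_table <- function(x, model, anchor = 3) {
  gal <- .as_gal(x, model)
  cov <- median_coverage(gal, model)
  exon_cov <- filter(cov, .data$kind == "exon") |>
    select(exon = "index", "median_cov") |>
    arrange(.data$exon)
  intron_cov <- filter(cov, .data$kind == "intron") |>
    select(intron = "index", intron_median = "median_cov")
  tbl <- count_boundary_reads(gal, model, anchor) |>
    compute_ssi() |>
    left_join(intron_cov, by = "intron") |>
    mutate(exon5_median = exon_cov$median_cov[match(.data$intron,
                                                    exon_cov$exon)],
           exon3_median = exon_cov$median_cov[match(.data$intron + 1L,
                                                    exon_cov$exon)])
  structure(tbl, class = c("ssi_table", class(tbl)),
            exon_coverage = exon_cov, gene_id = model$gene_id)
}

#' Rank introns by retention evidence
#'
#' A retained intron keeps unspliced boundaries at both of its splice
#' sites, so both SSI5 and SSI3 should be low. The retention magnitude of
#' intron i is the mean of `1 - SSI5` and `1 - SSI3` (joint lowness); its
#' empirical p-value is the fraction of the other introns with magnitude at
#' least as large. Because the two readings of "magnitude" differ in the
#' field, the asymmetry `|SSI5 - SSI3|` is reported as a separate column.
#'
#' @param tbl Tibble with `intron`, `SSI5`, `SSI3` (e.g. an `ssi_table`).
#' @param alpha Candidate threshold on the empirical p-value (default 0.1).
#' @return Tibble sorted by descending magnitude (ties broken by ascending
#'   intron index): `intron`, `magnitude`, `asymmetry`, `p_value`,
#'   `candidate`. `candidate` is `TRUE` only for introns holding the maximum
#'   magnitude with `p_value < alpha`.
#' @export
rank_intron_retention <- function(tbl, alpha = 0.1) {
  ok <- filter(tbl, !is.na(.data$SSI5), !is.na(.data$SSI3))
  if (nrow(ok) < 3) {
    abort(sprintf("retention ranking needs >= 3 introns with defined SSI on both sites, got %d",
                  nrow(ok)),
          class = "splicestage_too_few_introns")
  }
  mag <- (1 - ok$SSI5 + 1 - ok$SSI3) / 2
  p <- vapply(seq_along(mag),
              function(i) mean(mag[-i] >= mag[i]), numeric(1))
  tibble(intron = ok$intron,
         magnitude = mag,
         asymmetry = abs(ok$SSI5 - ok$SSI3),
         p_value = p,
         candidate = mag == max(mag) & mag > 0 & p < alpha) |>
    arrange(desc(.data$magnitude), .data$intron)
}
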