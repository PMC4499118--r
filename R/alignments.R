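#' Read alignments overlapping a gene
#'
#' Thin wrapper over [GenomicAlignments::readGAlignments()] keeping the SAM
#' flag, dropping secondary and supplementary records (the intended input is
#' an aligner emitting one alignment per read). Split alignments must encode
#' skipped regions as CIGAR `N` operations.
#'
#' @param bam Path to a BAM file (indexed if `model` is used for region
#'   restriction).
#' @param model Optional [gene_model()]; when given only alignments
#'   overlapping the gene span are read.
#' @return A `GAlignments` object with a `flag` metadata column and read
#'   names.
#' @export
read_gene_alignments <- function(bam, model = NULL) {
  flag <- scanBamFlag(isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE,
                      isUnmappedQuery = FALSE)
  param <- if (is.null(model)) {
    ScanBamParam(what = "flag", flag = flag)
  } else {
    sp <- gene_span(model)
    ScanBamParam(what = "flag", flag = flag,
                 which = GRanges(model$chrom, IRanges(sp[1], sp[2])))
  }
  readGAlignments(bam, param = param, use.names = TRUE)
}

.as_gal <- function(x, model = NULL) {
  if (is.character(x)) read_gene_alignments(x, model) else x
}

# M/D blocks per alignment on the reference (N gaps split blocks, D does not)
.ref_blocks <- function(gal) {
  GenomicAlignments::extractAlignmentRangesOnReference(
    cigar(gal), pos = start(gal), drop.D.ranges = FALSE)
}

# one row per N gap: alignment row, gap interval, flanking block widths
.gap_table <- function(gal) {
  irl <- .ref_blocks(gal)
  nb <- S4Vectors::elementNROWS(irl)
  ir <- unlist(irl, use.names = FALSE)
  grp <- rep(seq_along(gal), nb)
  k <- which(head(grp, -1) == tail(grp, -1))
  tibble(
    row = grp[k],
    gap_start = end(ir)[k] + 1L,
    gap_end = start(ir)[k + 1L] - 1L,
    left_w = width(ir)[k],
    right_w = width(ir)[k + 1L]
  )
}

.mate_of <- function(flag) {
  ifelse(bitwAnd(flag, 1L) == 0L, NA_integer_,
         ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L))
}

#' Label aligned read ends by the features they map to
#'
#' Each aligned end gets exactly one label: `int` (fully intronic), `ex`
#' (fully within one exon), `ex-int` (contiguous across an exon/intron
#' border), `ex-ex` (split alignment whose gap(s) exactly match annotated
#' introns, with all aligned blocks exonic), `other` (split with a
#' non-annotated gap; excluded from pair classification but the raw material
#' of recursive-splicing detection), or `outside` (partly outside the gene
#' span).
#'
#' @param x BAM path or `GAlignments` from [read_gene_alignments()].
#' @param model A [gene_model()].
#' @return Tibble, one row per end: `row` (alignment index), `qname`,
#'   `mate` (1/2, `NA` if unpaired), `label`, `feat_idx` (intron index for
#'   `int`, exon index for `ex`, else `NA`), `jx` (list column of intron
#'   indices whose junctions an `ex-ex` end spans), `gstart`, `gend`
#'   (leftmost/rightmost aligned base).
#' @export
label_ends <- function(x, model) {
  gal <- .as_gal(x, model)
  n <- length(gal)
  out <- tibble(
    row = seq_len(n),
    qname = if (is.null(names(gal))) rep(NA_character_, n) else names(gal),
    mate = .mate_of(mcols(gal)$flag %||% rep(0L, n)),
    label = rep(NA_character_, n),
    feat_idx = rep(NA_integer_, n),
    jx = vector("list", n),
    gstart = start(gal),
    gend = end(gal)
  )
  if (n == 0) return(out)

  span <- gene_span(model)
  ft <- feature_table(model)
  same_chrom <- as.character(seqnames(gal)) == model$chrom

  irl <- .ref_blocks(gal)
  nb <- S4Vectors::elementNROWS(irl)
  ir <- unlist(irl, use.names = FALSE)
  grp <- rep(seq_len(n), nb)
  bs <- start(ir); be <- end(ir)
  b_out <- bs < span[1] | be > span[2]
  f1 <- findInterval(bs, ft$start)
  f2 <- findInterval(be, ft$start)
  f1[b_out] <- NA_integer_; f2[b_out] <- NA_integer_
  b_exonic <- !b_out & f1 == f2 & ft$kind[pmax(f1, 1L)] == "exon"

  per_end <- tibble(grp = grp, b_out = b_out, f1 = f1, f2 = f2,
                    b_exonic = b_exonic) |>
    group_by(.data$grp) |>
    summarise(any_out = any(.data$b_out),
              all_exonic = all(.data$b_exonic),
              first_f = .data$f1[1],
              last_f = .data$f2[dplyr::n()],
              nb = dplyr::n(), .groups = "drop")

  # split ends: do all gaps match annotated introns (exact coordinates)?
  gt <- .gap_table(gal)
  intron_key <- paste(model$introns$start, model$introns$end)
  gt$ann <- match(paste(gt$gap_start, gt$gap_end), intron_key)
  gap_ok <- gt |>
    group_by(.data$row) |>
    summarise(all_ann = all(!is.na(.data$ann)),
              jx = list(sort(model$introns$intron[.data$ann[!is.na(.data$ann)]])),
              .groups = "drop")

  lab <- character(n)
  fi <- rep(NA_integer_, n)
  o <- per_end$grp
  single <- per_end$nb == 1L
  same_feat <- !per_end$any_out & per_end$first_f == per_end$last_f

  lab[o[per_end$any_out]] <- "outside"
  u <- !per_end$any_out
  # contiguous ends
  k <- u & single & same_feat
  lab[o[k]] <- ifelse(ft$kind[per_end$first_f[k]] == "exon", "ex", "int")
  fi[o[k]] <- ft$index[per_end$first_f[k]]
  k <- u & single & !same_feat
  lab[o[k]] <- "ex-int"
  # split ends
  k <- u & !single
  ok <- rep(FALSE, n); jxl <- vector("list", n)
  ok[gap_ok$row] <- gap_ok$all_ann
  jxl[gap_ok$row] <- gap_ok$jx
  kk <- o[k]
  is_exex <- ok[kk] & per_end$all_exonic[k]
  lab[kk] <- ifelse(is_exex, "ex-ex", "other")
  out$jx[kk[is_exex]] <- jxl[kk[is_exex]]

  lab[!same_chrom] <- "outside"
  out$label <- lab
  out$feat_idx <- fi
  out
}

#' Label a single read end given its aligned blocks
#'
#' Convenience scalar form of [label_ends()] for one end described by its
#' aligned reference blocks (split alignments give two or more blocks; the
#' gaps between consecutive blocks are the skipped regions).
#'
#' @param blocks Data frame with `start`, `end` (sorted, non-overlapping
#'   aligned blocks, 1-based inclusive).
#' @param model A [gene_model()].
#' @return Single label string (see [label_ends()]).
#' @export
#' @examples
#' gm <- gene_model("G", "chr1", "+",
#'                  data.frame(start = c(101, 301, 501),
#'                             end   = c(200, 400, 600)))
#' label_end(data.frame(start = 150, end = 160), gm)           # "ex"
#' label_end(data.frame(start = c(190, 301), end = c(200, 310)), gm) # "ex-ex"
label_end <- function(blocks, model) {
  blocks <- arrange(as_tibble(blocks), .data$start)
  cig <- paste0(blocks$end - blocks$start + 1L, "M")
  if (nrow(blocks) > 1) {
    gaps <- blocks$start[-1] - blocks$end[-nrow(blocks)] - 1L
    if (any(gaps < 1)) abort("blocks overlap or touch")
    cig <- c(cig[1], paste0(gaps, "N", cig[-1]))
  }
  gal <- GenomicAlignments::GAlignments(
    seqnames = model$chrom, pos = as.integer(blocks$start[1]),
    cigar = paste(cig, collapse = ""), strand = S4Vectors::Rle(factor("*", levels = c("+", "-", "*"))))
  label_ends(gal, model)$label
}

#' Inner mapping distance between the two ends of a read pair
#'
#' The genomic gap between the rightmost aligned base of the leftmost end
#' and the leftmost aligned base of the rightmost end; 0 when the ends touch
#' or overlap, never negative.
#'
#' @param end1,end2 Data frames with `start`, `end` columns (aligned blocks
#'   of each end).
#' @return Non-negative integer distance in bases.
#' @export
#' @examples
#' mapping_distance(data.frame(start = 100, end = 199),
#'                  data.frame(start = 300, end = 399)) # 100
mapping_distance <- function(end1, end2) {
  .pair_distance(min(end1$start), max(end1$end), min(end2$start), max(end2$end))
}

.pair_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}
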