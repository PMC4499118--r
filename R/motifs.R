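#' Splice-motif analysis of recursive-splicing events
#'
#' For each junction the donor motif is the first two intronic (removed)
#' bases 3' of the donor site and the acceptor motif the last two removed
#' bases 5' of the acceptor, read on the coding strand (reverse-complemented
#' for minus-strand genes); canonical splicing leaves GT at the donor and AG
#' at the acceptor. The two exonic/retained bases flanking each site are
#' reported alongside. The summary gives the percentage of canonical motifs
#' at the *novel* site among events with exactly one non-annotated site,
#' stratified by the number of supporting samples; events with two novel
#' sites are omitted from percentages as they are more likely novel exons.
#'
#' @param events Tibble from [classify_events()] (or a [junction_matrix()];
#'   events are then typed first).
#' @param genome A `DNAStringSet` (or FASTA path) containing the gene's
#'   contig.
#' @param model A [gene_model()].
#' @return List with `events` (per-event motifs and `canonical_donor` /
#'   `canonical_acceptor` / `canonical_novel_site` flags) and `summary`
#'   (per `n_samples` stratum: events considered and `% canonical`).
#' @export
motif_analysis <- function(events, genome, model) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!model$chrom %in% names(genome)) {
    abort(sprintf("contig '%s' not in genome", model$chrom))
  }
  seq <- genome[[model$chrom]]
  if (!"type" %in% names(events)) events <- classify_events(events, model)
  minus <- model$strand == "-"

  # genomic gap extent back from the splice-site coordinates
  gs <- if (minus) events$acceptor + 1L else events$donor + 1L
  ge <- if (minus) events$donor - 1L else events$acceptor - 1L

  edge <- gs - 3L < 1L | ge + 3L > length(seq)
  if (any(edge)) {
    warn(sprintf("%d event(s) too close to the contig edge were skipped",
                 sum(edge)))
    events <- events[!edge, ]; gs <- gs[!edge]; ge <- ge[!edge]
  }

  fetch <- function(s, e) {
    x <- as.character(Biostrings::extractAt(seq, IRanges(s, e)))
    if (minus) {
      x <- as.character(reverseComplement(DNAStringSet(x)))
    }
    x
  }
  if (nrow(events) > 0) {
    if (!minus) {
      donor_motif <- fetch(gs, gs + 1L)        # first 2 intronic bases
      acceptor_motif <- fetch(ge - 1L, ge)     # last 2 intronic bases
      donor_flank <- fetch(gs - 2L, gs - 1L)   # 2 exonic/retained bases
      acceptor_flank <- fetch(ge + 1L, ge + 2L)
    } else {
      donor_motif <- fetch(ge - 1L, ge)
      acceptor_motif <- fetch(gs, gs + 1L)
      donor_flank <- fetch(ge + 1L, ge + 2L)
      acceptor_flank <- fetch(gs - 2L, gs - 1L)
    }
  } else {
    donor_motif <- acceptor_motif <- donor_flank <- acceptor_flank <-
      character(0)
  }

  ev <- as_tibble(events) |>
    mutate(donor_motif = donor_motif,
           acceptor_motif = acceptor_motif,
           donor_flank = donor_flank,
           acceptor_flank = acceptor_flank,
           canonical_donor = donor_motif == "GT",
           canonical_acceptor = acceptor_motif == "AG",
           canonical_novel_site = case_when(
             .data$type == "5prime_recursive" ~ .data$canonical_acceptor,
             .data$type == "3prime_recursive" ~ .data$canonical_donor,
             TRUE ~ NA
           ))

  summary <- ev |>
    filter(.data$type %in% c("5prime_recursive", "3prime_recursive")) |>
    group_by(n_samples = .data$n_samples) |>
    summarise(n_events = dplyr::n(),
              pct_canonical = 100 * mean(.data$canonical_novel_site),
              .groups = "drop")

  list(events = ev, summary = summary)
}

#' Flag putative novel exons between consensus split peaks
#'
#' An intra-intronic interval bounded by a split end (negative peak at its
#' left edge) and a following split start (positive peak just past its
#' right edge) whose median coverage clearly exceeds its host intron's is
#' more likely an unannotated exon than a recursive-splicing intermediate:
#' flanking split reads plus elevated retained coverage is the novel-exon
#' signature. Flagged intervals should be excluded from the recursive event
#' list (see [exclude_novel_exon_events()]); definitive disambiguation
#' requires assaying nuclear vs cytoplasmic RNA and is out of scope.
#'
#' @param consensus Tibble from [consensus_peaks()].
#' @param x BAM path or `GAlignments` (for per-base coverage), or a
#'   coverage tibble from [median_coverage()] is not accepted -- raw
#'   alignments are needed for within-interval medians.
#' @param model A [gene_model()].
#' @param k Coverage-ratio threshold: flag when the interval's median
#'   coverage exceeds `k` times the containing intron's median (default 2).
#' @return Tibble of candidate intervals: `start`, `end`, `intron`,
#'   `interval_median`, `intron_median`, `flagged`.
#' @export
flag_novel_exons <- function(consensus, x, model, k = 2) {
  empty <- tibble(start = integer(), end = integer(), intron = integer(),
                  interval_median = numeric(), intron_median = numeric(),
                  flagged = logical())
  neg <- sort(consensus$pos[consensus$sign == -1L])
  pos <- sort(consensus$pos[consensus$sign == 1L])
  if (length(neg) == 0 || length(pos) == 0) return(empty)

  # interval of retained bases between a gap closing (at neg) and the next
  # gap opening (at pos): [neg, pos - 1]
  cand <- purrr::map(neg, function(p1) {
    p2 <- pos[pos > p1]
    if (length(p2) == 0) return(NULL)
    tibble(start = p1, end = min(p2) - 1L)
  }) |>
    list_rbind()
  if (is.null(cand) || nrow(cand) == 0) return(empty)

  gal <- .as_gal(x, model)
  span <- gene_span(model)
  cov <- coverage(gal)
  v <- if (model$chrom %in% names(cov)) as.numeric(cov[[model$chrom]]) else numeric(0)
  if (length(v) < span[2]) v <- c(v, numeric(span[2] - length(v)))

  introns <- model$introns
  host <- function(s, e) {
    i <- which(introns$start <= s & introns$end >= e)
    if (length(i) == 1) introns$intron[i] else NA_integer_
  }
  cov_tbl <- median_coverage(gal, model) |> filter(.data$kind == "intron")

  cand |>
    mutate(intron = purrr::map2_int(.data$start, .data$end, host)) |>
    filter(!is.na(.data$intron), .data$end >= .data$start) |>
    mutate(
      interval_median = purrr::map2_dbl(.data$start, .data$end,
                                        ~ median(v[.x:.y])),
      intron_median = cov_tbl$median_cov[match(.data$intron, cov_tbl$index)],
      flagged = .data$interval_median > k * .data$intron_median
    )
}

#' Drop recursive events that bound a flagged novel-exon interval
#'
#' @param events Event tibble ([classify_events()] output).
#' @param novel Tibble from [flag_novel_exons()].
#' @param model A [gene_model()].
#' @return `events` without junctions whose gap closes into (acceptor-side)
#'   or opens out of (donor-side) a flagged interval.
#' @export
exclude_novel_exon_events <- function(events, novel, model) {
  fl <- filter(novel, .data$flagged)
  if (nrow(fl) == 0) return(events)
  minus <- model$strand == "-"
  # gap end + 1 (genomic) and gap start - 1 back from splice-site coords
  gap_close <- if (minus) events$donor else events$acceptor
  gap_open_minus1 <- if (minus) events$acceptor else events$donor
  drop <- gap_close %in% fl$start | gap_open_minus1 %in% fl$end
  events[!drop, ]
}
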