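#' Extract non-annotated split-read gaps over a gene
#'
#' Every CIGAR `N` gap of every read end overlapping the gene is emitted,
#' except gaps exactly matching an annotated intron (those indicate ordinary
#' splicing at an annotated junction and carry no recursive-splicing
#' information). The two ends of a pair are treated independently.
#'
#' @param x BAM path or `GAlignments`.
#' @param model A [gene_model()].
#' @return Tibble, one row per retained gap: `qname`, `gap_start`,
#'   `gap_end` (first/last skipped base), `donor` (last aligned base before
#'   the gap), `acceptor` (first aligned base after the gap), `left_w`,
#'   `right_w` (flanking block widths).
#' @export
extract_gaps <- function(x, model) {
  gal <- .as_gal(x, model)
  gt <- .gap_table(gal)
  if (nrow(gt) == 0) {
    return(tibble(qname = character(), gap_start = integer(),
                  gap_end = integer(), donor = integer(),
                  acceptor = integer(), left_w = integer(),
                  right_w = integer()))
  }
  span <- gene_span(model)
  ann <- paste(model$introns$start, model$introns$end)
  qn <- if (is.null(names(gal))) rep(NA_character_, length(gal)) else names(gal)
  gt |>
    filter(!(paste(.data$gap_start, .data$gap_end) %in% ann),
           .data$gap_end >= span[1], .data$gap_start <= span[2]) |>
    transmute(qname = qn[.data$row],
              gap_start = .data$gap_start, gap_end = .data$gap_end,
              donor = .data$gap_start - 1L, acceptor = .data$gap_end + 1L,
              left_w = .data$left_w, right_w = .data$right_w)
}

#' Signed peaks of inverted gap coverage
#'
#' The *inverted coverage* of a position is the number of retained split
#' gaps covering it. Its derivative (value at p minus value at p-1) is
#' non-zero exactly where gaps open or close: a gap over the closed
#' interval `[s, e]` contributes a positive peak of its count at `s` (split
#' start) and a negative peak at `e + 1` (split end). Positions that are a
#' split start for some reads and a split end for others are excluded.
#'
#' @param gaps Tibble from [extract_gaps()].
#' @return Object of class `gap_peaks`: tibble `pos`, `sign` (+1/-1),
#'   `magnitude` (number of gaps opening/closing there), with attribute
#'   `n_gaps` (retained gap count). The gap-conservation identity -- sum of
#'   positive magnitudes = sum of negative magnitudes = `n_gaps`, before
#'   the both-start-and-end exclusion -- holds by construction.
#' @export
gap_peaks <- function(gaps) {
  starts <- table(gaps$gap_start)
  ends <- table(gaps$gap_end + 1L)
  sp <- as.integer(names(starts)); ep <- as.integer(names(ends))
  both <- intersect(sp, ep)
  pk <- bind_rows(
    tibble(pos = sp, sign = 1L, magnitude = as.integer(starts)),
    tibble(pos = ep, sign = -1L, magnitude = as.integer(ends))
  ) |>
    filter(!(.data$pos %in% both)) |>
    arrange(.data$pos, desc(.data$sign))
  structure(pk, class = c("gap_peaks", class(pk)),
            n_gaps = nrow(gaps), n_excluded_pos = length(both))
}

#' Inverted coverage vector of split gaps
#'
#' @param gaps Tibble from [extract_gaps()].
#' @param from,to Region (defaults to the gap extent).
#' @return Tibble `pos`, `inverted_coverage`.
#' @export
inverted_coverage <- function(gaps, from = NULL, to = NULL) {
  if (nrow(gaps) == 0) return(tibble(pos = integer(),
                                     inverted_coverage = integer()))
  from <- from %||% min(gaps$gap_start)
  to <- to %||% max(gaps$gap_end)
  pos <- from:to
  cov <- integer(length(pos))
  for (k in seq_len(nrow(gaps))) {
    i <- max(gaps$gap_start[k], from):min(gaps$gap_end[k], to) - from + 1L
    cov[i] <- cov[i] + 1L
  }
  tibble(pos = pos, inverted_coverage = cov)
}

#' Cross-sample consensus of signed gap peaks
#'
#' A position is retained when it carries a peak of the same sign, with
#' per-sample magnitude of at least `min_magnitude`, in at least
#' `min_samples` samples; the reported value is the summed magnitude across
#' all samples containing it. Requiring two or more reads per sample
#' excludes the singleton split positions that dominate DNA controls.
#'
#' @param peaks Named list of per-sample [gap_peaks()] tibbles.
#' @param min_samples Minimum number of supporting samples.
#' @param min_magnitude Minimum per-sample peak magnitude (default 2).
#' @return Tibble `pos`, `sign`, `n_samples`, `magnitude` (summed).
#' @export
consensus_peaks <- function(peaks, min_samples = length(peaks),
                            min_magnitude = 2) {
  stopifnot(length(peaks) >= 1)
  if (min_samples > length(peaks)) {
    abort(sprintf("min_samples (%d) exceeds number of samples (%d)",
                  min_samples, length(peaks)),
          class = "splicestage_min_samples")
  }
  if (is.null(names(peaks)) || any(names(peaks) == "")) {
    names(peaks) <- paste0("sample", seq_along(peaks))
  }
  purrr::imap(peaks, ~ mutate(as_tibble(.x), sample = .y)) |>
    list_rbind() |>
    filter(.data$magnitude >= min_magnitude) |>
    group_by(.data$pos, .data$sign) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample),
              magnitude = sum(.data$magnitude), .groups = "drop") |>
    filter(.data$n_samples >= min_samples) |>
    arrange(.data$pos)
}

#' Donor-by-acceptor junction matrix from consensus positions
#'
#' Split reads whose gap opens at a consensus positive peak and closes at a
#' consensus negative peak are re-extracted from the per-sample gap tables
#' (recovering the peak-to-peak connections that the per-position wiggle
#' representation loses) and tallied per (donor, acceptor) junction. Donor
#' and acceptor are reported as splice-site bases: the last aligned base
#' before the gap and the first aligned base after it. Each junction is
#' annotated for whether its donor/acceptor coincides with an annotated
#' exon/intron border (strand-aware: on the minus strand the donor is the
#' right-hand site).
#'
#' @param gaps_by_sample Named list of per-sample [extract_gaps()] tibbles.
#' @param consensus Tibble from [consensus_peaks()].
#' @param model A [gene_model()].
#' @return Object of class `junction_matrix`: tibble `donor`, `acceptor`,
#'   `count`, `n_samples`, `donor_annotated`, `acceptor_annotated`. Use
#'   [as.matrix()] for the donor-columns-by-acceptor-rows layout.
#' @export
junction_matrix <- function(gaps_by_sample, consensus, model) {
  pos_plus <- consensus$pos[consensus$sign == 1L]
  pos_minus <- consensus$pos[consensus$sign == -1L]
  if (is.null(names(gaps_by_sample)) || any(names(gaps_by_sample) == "")) {
    names(gaps_by_sample) <- paste0("sample", seq_along(gaps_by_sample))
  }
  all_gaps <- purrr::imap(gaps_by_sample, ~ mutate(.x, sample = .y)) |>
    list_rbind() |>
    filter(.data$gap_start %in% pos_plus,
           (.data$gap_end + 1L) %in% pos_minus)

  ann_donor <- model$junctions$donor
  ann_acceptor <- model$junctions$acceptor
  jm <- all_gaps |>
    group_by(.data$gap_start, .data$gap_end) |>
    summarise(count = dplyr::n(),
              n_samples = dplyr::n_distinct(.data$sample),
              .groups = "drop") |>
    mutate(
      donor = if (model$strand == "+") .data$gap_start - 1L
              else .data$gap_end + 1L,
      acceptor = if (model$strand == "+") .data$gap_end + 1L
                 else .data$gap_start - 1L,
      donor_annotated = .data$donor %in% ann_donor,
      acceptor_annotated = .data$acceptor %in% ann_acceptor
    ) |>
    select("donor", "acceptor", "count", "n_samples",
           "donor_annotated", "acceptor_annotated") |>
    arrange(.data$donor, .data$acceptor)
  structure(jm, class = c("junction_matrix", class(jm)),
            strand = model$strand, gene_id = model$gene_id)
}

#' @export
as.matrix.junction_matrix <- function(x, ...) {
  donors <- sort(unique(x$donor))
  acceptors <- sort(unique(x$acceptor))
  m <- matrix(0L, nrow = length(acceptors), ncol = length(donors),
              dimnames = list(acceptor = acceptors, donor = donors))
  m[cbind(match(x$acceptor, acceptors), match(x$donor, donors))] <- x$count
  m
}

#' Classify recursive-splicing events by splice-site annotation
#'
#' Events with an annotated donor and an intra-intronic acceptor are
#' 5'-recursive (the first removal step keeps the canonical donor); an
#' annotated acceptor with a novel donor is 3'-recursive; two novel sites
#' is an inner event (a candidate novel exon or lariat-type removal); two
#' annotated sites (an exon-skipping-like gap between non-adjacent
#' borders) is labelled `skip_like`. Junctions sharing one annotated site
#' are grouped as potential multi-step chains.
#'
#' @param jm A [junction_matrix()].
#' @param model A [gene_model()].
#' @return Tibble: the junction rows plus `type` and `chain_group` (a group
#'   id shared by junctions with a common annotated site; `NA` for
#'   ungrouped events).
#' @export
classify_events <- function(jm, model) {
  ev <- as_tibble(jm) |>
    mutate(type = case_when(
      .data$donor_annotated & .data$acceptor_annotated ~ "skip_like",
      .data$donor_annotated & !.data$acceptor_annotated ~ "5prime_recursive",
      !.data$donor_annotated & .data$acceptor_annotated ~ "3prime_recursive",
      TRUE ~ "inner"
    ))
  # multi-step chains: >= 2 events sharing one annotated donor or acceptor
  grp <- rep(NA_integer_, nrow(ev))
  gid <- 0L
  for (site in c("donor", "acceptor")) {
    annotated <- ev[[paste0(site, "_annotated")]]
    shared <- ev[[site]][annotated]
    for (s in unique(shared[duplicated(shared)])) {
      gid <- gid + 1L
      grp[ev[[site]] == s & annotated] <- gid
    }
  }
  ev$chain_group <- grp
  ev
}
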