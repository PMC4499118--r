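#' Build a gene model from exon coordinates
#'
#' A gene model is the single reference transcript every downstream stage
#' queries: ordered exons, the introns derived as the gaps between
#' consecutive exons, and the annotated (donor, acceptor) junction
#' coordinates, one per intron. Exons and introns are numbered in
#' transcription order, so on the minus strand exon 1 is the exon with the
#' highest genomic coordinate; genomic coordinates themselves are never
#' flipped. All coordinates are 1-based and inclusive, as in GTF and SAM.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start` and `end` (genomic, 1-based
#'   inclusive), one row per exon, in any order. At least two exons are
#'   required: a single-exon gene has no introns to analyse.
#'
#' @return An object of class `gene_model`: a list with `gene_id`, `chrom`,
#'   `strand`, `exons`, `introns` (tibbles with transcription-order indices),
#'   and `junctions` (tibble with `intron`, `donor`, `acceptor`, the genomic
#'   coordinates of the exonic bases flanking each intron at its
#'   transcriptional 5' and 3' side).
#' @export
#' @examples
#' gm <- gene_model("G", "chr1", "+",
#'                  data.frame(start = c(101, 301, 501),
#'                             end   = c(200, 400, 600)))
#' gm$introns
gene_model <- function(gene_id, chrom, strand, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1)
  if (!strand %in% c("+", "-")) {
    abort(sprintf("strand must be '+' or '-', got '%s'", strand),
          class = "splicestage_bad_strand")
  }
  exons <- as_tibble(exons)[, c("start", "end")]
  exons <- arrange(exons, .data$start)
  if (nrow(exons) < 2) {
    abort(sprintf("gene '%s' has %d exon(s): no introns to analyze",
                  gene_id, nrow(exons)),
          class = "splicestage_single_exon")
  }
  if (any(exons$end < exons$start)) {
    abort("exon end < start", class = "splicestage_bad_interval")
  }
  if (any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort(sprintf("gene '%s': exons overlap or touch; introns undefined",
                  gene_id),
          class = "splicestage_overlapping_exons")
  }

  n <- nrow(exons)
  # transcription-order numbering; genomic order is ascending
  ex_idx <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  exons$exon <- ex_idx
  introns <- tibble(
    start = exons$end[-n] + 1L,
    end   = exons$start[-1] - 1L
  )
  # intron between genomic exon k and k+1 carries the transcription index of
  # its upstream exon: i on '+', and on '-' the upstream exon is the right one
  introns$intron <- if (strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))

  exons   <- select(arrange(exons, .data$exon), "exon", "start", "end")
  introns <- select(arrange(introns, .data$intron), "intron", "start", "end")

  junctions <- if (strand == "+") {
    tibble(intron = introns$intron,
           donor = introns$start - 1L, acceptor = introns$end + 1L)
  } else {
    tibble(intron = introns$intron,
           donor = introns$end + 1L, acceptor = introns$start - 1L)
  }

  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, introns = introns, junctions = junctions),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s:%d-%d, %s strand): %d exons, %d introns\n",
              x$gene_id, x$chrom, gene_span(x)[1], gene_span(x)[2],
              x$strand, nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param model A [gene_model()].
#' @return Integer vector `c(start, end)` (1-based inclusive).
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' All features of a gene model in genomic order
#'
#' @param model A [gene_model()].
#' @return Tibble with `kind` (`"exon"`/`"intron"`), `index` (transcription
#'   order), `start`, `end`, sorted by genomic start. Exons and introns tile
#'   the gene span contiguously.
#' @export
feature_table <- function(model) {
  bind_rows(
    mutate(model$exons,   kind = "exon",   index = .data$exon),
    mutate(model$introns, kind = "intron", index = .data$intron)
  ) |>
    select("kind", "index", "start", "end") |>
    arrange(.data$start)
}

#' Locate a genomic interval within a gene model
#'
#' Reports which single exon or intron fully contains the interval, whether
#' it straddles one or more exon/intron boundaries, or whether it falls
#' (partly) outside the gene span.
#'
#' @param model A [gene_model()].
#' @param start,end Genomic interval, 1-based inclusive.
#' @param chrom Optional chromosome; if given and different from the model's,
#'   an error of class `splicestage_wrong_chrom` is raised.
#' @return One-row tibble: `kind` one of `"exon"`, `"intron"`, `"boundary"`,
#'   `"outside"`; `index` the feature index (`NA` unless kind is
#'   exon/intron); `first_kind`/`first_index` and `last_kind`/`last_index`
#'   give the features containing the interval's two endpoints (NA when
#'   outside).
#' @export
locate_feature <- function(model, start, end, chrom = NULL) {
  if (!is.null(chrom) && !identical(chrom, model$chrom)) {
    abort(sprintf("interval on '%s' but gene model is on '%s'",
                  chrom, model$chrom),
          class = "splicestage_wrong_chrom")
  }
  stopifnot(end >= start)
  span <- gene_span(model)
  if (start < span[1] || end > span[2]) {
    return(tibble(kind = "outside", index = NA_integer_,
                  first_kind = NA_character_, first_index = NA_integer_,
                  last_kind = NA_character_, last_index = NA_integer_))
  }
  ft <- feature_table(model)
  i1 <- findInterval(start, ft$start)
  i2 <- findInterval(end, ft$start)
  if (i1 == i2) {
    tibble(kind = ft$kind[i1], index = ft$index[i1],
           first_kind = ft$kind[i1], first_index = ft$index[i1],
           last_kind = ft$kind[i2], last_index = ft$index[i2])
  } else {
    tibble(kind = "boundary", index = NA_integer_,
           first_kind = ft$kind[i1], first_index = ft$index[i1],
           last_kind = ft$kind[i2], last_index = ft$index[i2])
  }
}

#' Load gene models from a GTF file
#'
#' Reads an Ensembl-dialect GTF (attributes `gene_id`, `transcript_id`) and
#' builds one [gene_model()] per requested gene from a single reference
#' transcript. The pipeline compares everything against one reference
#' transcript per gene; by default the transcript with the most exons is
#' chosen, which can be overridden per gene.
#'
#' @param gtf Path to a GTF file.
#' @param gene_ids Character vector of gene ids to load; `NULL` loads every
#'   gene in the file.
#' @param transcript Optional named character vector mapping gene id to the
#'   transcript id to use instead of the most-exon default.
#' @return Named list of [gene_model()] objects (names are gene ids).
#' @export
read_gene_models <- function(gtf, gene_ids = NULL, transcript = NULL) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) abort("GTF has no feature type column")
  df <- filter(df, .data$type == "exon")
  if (!all(c("gene_id", "transcript_id") %in% names(df))) {
    abort("GTF lacks gene_id/transcript_id attributes (Ensembl dialect)")
  }
  if (is.null(gene_ids)) gene_ids <- unique(df$gene_id)
  missing <- setdiff(gene_ids, unique(df$gene_id))
  if (length(missing) > 0) {
    abort(sprintf("gene id(s) not found in GTF: %s",
                  paste(missing, collapse = ", ")),
          class = "splicestage_missing_gene")
  }
  models <- lapply(gene_ids, function(g) {
    dg <- filter(df, .data$gene_id == g)
    tx <- if (!is.null(transcript) && g %in% names(transcript)) {
      tid <- unname(transcript[[g]])
      if (!tid %in% dg$transcript_id) {
        abort(sprintf("transcript '%s' not found for gene '%s'", tid, g),
              class = "splicestage_missing_transcript")
      }
      tid
    } else {
      names(sort(table(dg$transcript_id), decreasing = TRUE))[1]
    }
    dt <- filter(dg, .data$transcript_id == tx)
    gene_model(g, as.character(dt$seqnames[1]), as.character(dt$strand[1]),
               tibble(start = dt$start, end = dt$end))
  })
  setNames(models, gene_ids)
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` row per exon (Ensembl attribute dialect), so that
#' [read_gene_models()] round-trips the model exactly.
#'
#' @param models A [gene_model()] or list of them.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  lines <- unlist(lapply(models, function(m) {
    ex <- arrange(m$exons, .data$start)
    # exon_number follows transcription order, as Ensembl does
    sprintf(
      paste0("%s\tsplicestage\texon\t%d\t%d\t.\t%s\t.\t",
             "gene_id \"%s\"; transcript_id \"%s.t1\"; exon_number \"%d\";"),
      m$chrom, ex$start, ex$end, m$strand, m$gene_id, m$gene_id, ex$exon
    )
  }))
  writeLines(lines, path)
  invisible(path)
}
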