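#' Assemble and validate a pipeline run configuration
#'
#' @param samples Data frame with columns `name`, `bam`, `role` (`"rna"` or
#'   `"dna_control"`; at most one control).
#' @param gtf Path to the gene annotation GTF.
#' @param gene_ids Genes to analyse (`NULL` = all in the GTF).
#' @param genome Optional FASTA path (enables motif analysis).
#' @param outdir Output directory.
#' @param transcript Optional named gene->transcript override (see
#'   [read_gene_models()]).
#' @param expected_distance,large_threshold,anchor,min_samples,ratio_cutoff,quartile,novel_exon_k,min_peak_magnitude
#'   Analysis thresholds; `min_samples` defaults to the number of RNA
#'   samples.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(samples, gtf, gene_ids = NULL, genome = NULL,
                            outdir = "splicestage_out",
                            transcript = NULL,
                            expected_distance = 650,
                            large_threshold = 650,
                            anchor = 3,
                            min_samples = NULL,
                            ratio_cutoff = 0.5,
                            quartile = "Q1",
                            novel_exon_k = 2,
                            min_peak_magnitude = 2) {
  samples <- as_tibble(samples)
  stopifnot(all(c("name", "bam", "role") %in% names(samples)))
  if (!all(samples$role %in% c("rna", "dna_control"))) {
    abort("sample roles must be 'rna' or 'dna_control'",
          class = "splicestage_bad_config")
  }
  if (sum(samples$role == "dna_control") > 1) {
    abort("at most one dna_control sample is allowed",
          class = "splicestage_bad_config")
  }
  missing <- samples$bam[!file.exists(samples$bam)]
  if (length(missing) > 0) {
    abort(paste0("BAM file(s) not found: ", paste(missing, collapse = ", ")),
          class = "splicestage_bad_config")
  }
  if (!file.exists(gtf)) {
    abort(sprintf("GTF not found: %s", gtf),
          class = "splicestage_bad_config")
  }
  n_rna <- sum(samples$role == "rna")
  structure(
    list(samples = samples, gtf = gtf, gene_ids = gene_ids,
         genome = genome, outdir = outdir, transcript = transcript,
         expected_distance = expected_distance,
         large_threshold = large_threshold, anchor = anchor,
         min_samples = min_samples %||% n_rna,
         ratio_cutoff = ratio_cutoff, quartile = quartile,
         novel_exon_k = novel_exon_k,
         min_peak_magnitude = min_peak_magnitude),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Expected keys: `samples` (list of `name`/`bam`/`role` entries), `gtf`,
#' and optionally `gene_ids`, `genome`, `outdir`, `transcript`, and a
#' `thresholds` mapping with any of the threshold arguments of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- purrr::map(y$samples, as_tibble) |> list_rbind()
  args <- c(
    list(samples = samples, gtf = y$gtf,
         gene_ids = y$gene_ids %||% NULL,
         genome = y$genome %||% NULL,
         outdir = y$outdir %||% "splicestage_out",
         transcript = unlist(y$transcript) %||% NULL),
    y$thresholds %||% list()
  )
  do.call(pipeline_config, args)
}

#' Run the full splicing analysis pipeline
#'
#' Per gene and sample: splicing-stage classification and the splice-site
#' table (SSI + coverage); per gene across samples: intron-retention
#' ranking, non-sequential calls with the DNA-control filter, per-sample
#' signed gap-peak wiggle tracks, consensus peaks, the junction matrix,
#' typed recursive events with motif analysis (when a genome FASTA is
#' given) and novel-exon flags. All result tables are returned and written
#' as TSV under `outdir/<gene>/`; every threshold in force is recorded in
#' `run_log.txt`.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @return Named list (per gene) of result lists, invisibly a side effect
#'   of the written output bundle.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  models <- read_gene_models(config$gtf, config$gene_ids, config$transcript)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  log_path <- file.path(config$outdir, "run_log.txt")
  log_lines <- c(
    sprintf("splicestage run: %d sample(s), %d gene(s)",
            nrow(config$samples), length(models)),
    sprintf("expected_distance=%s", config$expected_distance),
    sprintf("large_threshold=%s", config$large_threshold),
    sprintf("anchor=%s", config$anchor),
    sprintf("min_samples=%s", config$min_samples),
    sprintf("ratio_cutoff=%s", config$ratio_cutoff),
    sprintf("quartile=%s", config$quartile),
    sprintf("novel_exon_k=%s", config$novel_exon_k),
    sprintf("min_peak_magnitude=%s", config$min_peak_magnitude)
  )

  rna <- filter(config$samples, .data$role == "rna")
  ctrl <- filter(config$samples, .data$role == "dna_control")

  results <- purrr::imap(models, function(model, gid) {
    gdir <- file.path(config$outdir, gid)
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)

    gals <- lapply(setNames(config$samples$bam, config$samples$name),
                   function(b) {
                     tryCatch(read_gene_alignments(b, model),
                              error = function(e) {
                                abort(sprintf("cannot read '%s' for gene %s: %s",
                                              b, gid, conditionMessage(e)),
                                      class = "splicestage_io")
                              })
                   })
    empty <- names(gals)[vapply(gals, length, integer(1)) == 0]
    if (length(empty) > 0) {
      warn(sprintf("gene %s: no overlapping reads in sample(s) %s",
                   gid, paste(empty, collapse = ", ")))
    }

    cls <- purrr::imap(gals, ~ classify_sample(.x, model,
                                               config$expected_distance,
                                               config$large_threshold))
    cls_tbl <- purrr::imap(cls, ~ mutate(.x$summary, sample = .y)) |>
      list_rbind() |>
      select("sample", "category", "count", "fraction", "large_count")
    write_tsv(cls_tbl, file.path(gdir, "classification_summary.tsv"))

    ssi <- purrr::imap(gals, ~ splice_site_table(.x, model, config$anchor))
    ssi_tbl <- purrr::imap(ssi, ~ mutate(as_tibble(.x), sample = .y)) |>
      list_rbind() |>
      relocate("sample")
    write_tsv(ssi_tbl, file.path(gdir, "ssi_table.tsv"))

    retention <- purrr::imap(ssi[rna$name], function(s, nm) {
      tryCatch(mutate(rank_intron_retention(s), sample = nm),
               error = function(e) NULL)
    }) |>
      list_rbind()
    if (nrow(retention) > 0) {
      write_tsv(retention, file.path(gdir, "retention_ranking.tsv"))
    }

    ev_rna <- purrr::map(setNames(rna$name, rna$name), function(nm) {
      order_evidence(gals[[nm]], model, config$quartile,
                     config$expected_distance, config$large_threshold)
    })
    ev_ctrl <- if (nrow(ctrl) == 1) {
      order_evidence(gals[[ctrl$name]], model, config$quartile,
                     config$expected_distance, config$large_threshold)
    } else {
      NULL
    }
    calls <- call_nonsequential(ev_rna, ev_ctrl,
                                min_samples = config$min_samples,
                                ratio_cutoff = config$ratio_cutoff)
    write_tsv(as_tibble(calls), file.path(gdir, "order_calls.tsv"))

    gaps <- purrr::map(setNames(rna$name, rna$name),
                       ~ extract_gaps(gals[[.x]], model))
    peaks <- purrr::map(gaps, gap_peaks)
    purrr::iwalk(peaks, function(p, nm) {
      write_peaks_wig(p, file.path(gdir, paste0(nm, ".peaks.wig")),
                      model$chrom, paste0(nm, "_gap_peaks"))
    })
    consensus <- consensus_peaks(peaks, min_samples = config$min_samples,
                                 min_magnitude = config$min_peak_magnitude)
    write_peaks_wig(consensus, file.path(gdir, "consensus.peaks.wig"),
                    model$chrom, "consensus_gap_peaks")
    write_tsv(consensus, file.path(gdir, "consensus_peaks.tsv"))

    jm <- junction_matrix(gaps, consensus, model)
    write_tsv(as_tibble(jm), file.path(gdir, "junction_matrix.tsv"))
    events <- classify_events(jm, model)

    pooled <- do.call(c, unname(gals[rna$name]))
    novel <- flag_novel_exons(consensus, pooled, model,
                              k = config$novel_exon_k)
    if (nrow(novel) > 0) {
      write_tsv(novel, file.path(gdir, "novel_exons.tsv"))
    }
    events <- exclude_novel_exon_events(events, novel, model)

    motifs <- NULL
    if (!is.null(config$genome)) {
      motifs <- motif_analysis(events, config$genome, model)
      events <- motifs$events
    }
    write_tsv(as_tibble(events), file.path(gdir, "events.tsv"))

    list(model = model, classification = cls, ssi = ssi,
         retention = retention, order_calls = calls,
         consensus = consensus, junction_matrix = jm, events = events,
         novel_exons = novel, motifs = motifs)
  })

  writeLines(log_lines, log_path)
  results
}
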