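#' Configuration for the splicing-intermediate read simulator
#'
#' Defines a synthetic multi-intron locus and a paired-end library drawn
#' from a mixture of splicing stages. Defaults emulate a nuclear-RNA
#' capture library over a mid-sized gene: 100 bp paired ends, fragments
#' around 300 bp, and a stage mixture containing substantial unspliced
#' material alongside mature transcripts.
#'
#' @param n_exons Number of exons (>= 3); the gene has `n_exons - 1`
#'   introns.
#' @param exon_len,intron_len Length ranges (bases), `c(min, max)`.
#' @param strand `"+"` or `"-"`.
#' @param chrom Contig name.
#' @param flank Intergenic flank on each side (bases).
#' @param stage_mix Fractions of unspliced / partially spliced / mature
#'   molecules; must sum to 1.
#' @param order Splicing order as a permutation of intron indices
#'   (transcription numbering); `NULL` means sequential 5'->3'. Partially
#'   spliced molecules have removed a prefix of this order (snapshot
#'   semantics).
#' @param retention Per-intron retention probability (scalar recycled): a
#'   retained intron stays in the molecule even when its turn has come.
#' @param skip Per-exon skipping probability (scalar recycled); an interior
#'   exon can only be skipped once both flanking introns are removed.
#' @param recursive `NULL`, or a data frame with columns `intron`,
#'   `donor_offset` (bases of the intron's transcriptional 5' end retained
#'   before the first-step gap; 0 = annotated donor), `acceptor_offset`
#'   (offset of the first intron base *after* the gap, i.e. the gap removes
#'   intron bases `donor_offset+1 .. acceptor_offset` in transcription
#'   coordinates), and `usage` (fraction of intron-containing molecules
#'   carrying the partial gap). Canonical GT/AG motifs are planted at all
#'   annotated and recursive splice sites.
#' @param frag_mean,frag_sd,frag_min Fragment-size distribution: truncated
#'   normal, minimum `frag_min` (must be >= `read_len`).
#' @param read_len Read length (bases).
#' @param n_pairs Read pairs per sample.
#' @param n_molecules Size of the molecule pool pairs are drawn from.
#' @param error_rate Uniform substitution rate applied to read sequences
#'   (default 0: the pipeline operates downstream of alignment).
#' @param seed Integer seed; the locus is a deterministic function of the
#'   configuration.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_exons = 7,
                       exon_len = c(80, 200),
                       intron_len = c(250, 2000),
                       strand = "+",
                       chrom = "chrSim",
                       flank = 300,
                       stage_mix = c(unspliced = 0.4, partial = 0.2,
                                     mature = 0.4),
                       order = NULL,
                       retention = 0,
                       skip = 0,
                       recursive = NULL,
                       frag_mean = 300, frag_sd = 80, frag_min = 200,
                       read_len = 100,
                       n_pairs = 2000,
                       n_molecules = 1000,
                       error_rate = 0,
                       seed = 1) {
  n_introns <- n_exons - 1L
  stopifnot(n_exons >= 3, length(exon_len) == 2, length(intron_len) == 2)
  if (abs(sum(stage_mix) - 1) > 1e-8) {
    abort("stage_mix fractions must sum to 1", class = "splicestage_bad_sim")
  }
  if (frag_min < read_len) {
    abort("frag_min must be >= read_len", class = "splicestage_bad_sim")
  }
  if (is.null(order)) order <- seq_len(n_introns)
  if (!identical(sort(order), seq_len(n_introns)) &&
      !identical(sort(as.integer(order)), seq_len(n_introns))) {
    abort("order must be a permutation of the intron indices",
          class = "splicestage_bad_sim")
  }
  retention <- rep_len(retention, n_introns)
  skip <- rep_len(skip, n_exons)
  if (!is.null(recursive)) {
    recursive <- as_tibble(recursive)
    stopifnot(all(c("intron", "acceptor_offset", "usage") %in%
                    names(recursive)))
    if (!"donor_offset" %in% names(recursive)) recursive$donor_offset <- 0L
    if (any(recursive$usage < 0 | recursive$usage > 1)) {
      abort("recursive usage fractions must lie in [0, 1]",
            class = "splicestage_bad_sim")
    }
    if (any(recursive$acceptor_offset <= recursive$donor_offset + 4)) {
      abort("acceptor_offset must exceed donor_offset by > 4 bases",
            class = "splicestage_bad_sim")
    }
  }
  structure(
    list(n_exons = as.integer(n_exons), n_introns = n_introns,
         exon_len = exon_len, intron_len = intron_len,
         strand = strand, chrom = chrom, flank = as.integer(flank),
         stage_mix = stage_mix, order = as.integer(order),
         retention = retention, skip = skip, recursive = recursive,
         frag_mean = frag_mean, frag_sd = frag_sd, frag_min = frag_min,
         read_len = as.integer(read_len), n_pairs = as.integer(n_pairs),
         n_molecules = as.integer(n_molecules),
         error_rate = error_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a gene locus with planted splice motifs
#'
#' Draws exon/intron lengths, lays the gene on a random sequence and plants
#' canonical GT/AG dinucleotides at every annotated splice site and at
#' every configured recursive site (strand-aware). Deterministic under the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_locus`: list with `genome` (`DNAStringSet`),
#'   `model` ([gene_model()]), `recursive` (events resolved to genomic
#'   coordinates: `intron`, `gap_start`, `gap_end`, `donor`, `acceptor`,
#'   `usage`), `config`.
#' @export
simulate_locus <- function(config) {
  set.seed(config$seed)
  ne <- config$n_exons; ni <- config$n_introns
  el <- sample(config$exon_len[1]:config$exon_len[2], ne, replace = TRUE)
  il <- sample(config$intron_len[1]:config$intron_len[2], ni, replace = TRUE)

  # genomic layout, left to right: E I E I ... E
  widths <- integer(ne + ni)
  widths[seq(1, 2 * ne - 1, by = 2)] <- el
  widths[seq(2, 2 * ni, by = 2)] <- il
  starts <- config$flank + c(1L, 1L + cumsum(widths[-length(widths)]))
  ends <- starts + widths - 1L
  ex_g <- seq(1, 2 * ne - 1, by = 2)
  model <- gene_model("simGene", config$chrom, config$strand,
                      tibble(start = starts[ex_g], end = ends[ex_g]))

  total <- ends[length(ends)] + config$flank
  base <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  plant <- function(p, motif) {
    base[p:(p + nchar(motif) - 1L)] <<- strsplit(motif, "")[[1]]
  }
  donor_g <- if (config$strand == "+") "GT" else "CT"   # as + strand text
  accept_g <- if (config$strand == "+") "AG" else "AC"
  for (i in seq_len(nrow(model$introns))) {
    s <- model$introns$start[i]; e <- model$introns$end[i]
    if (config$strand == "+") {
      plant(s, "GT"); plant(e - 1L, "AG")
    } else {
      plant(s, "CT"); plant(e - 1L, "AC")   # revcomp: AG ... GT
    }
  }

  rec <- NULL
  if (!is.null(config$recursive)) {
    rec <- config$recursive
    if (any(!rec$intron %in% model$introns$intron)) {
      abort("recursive event on unknown intron",
            class = "splicestage_bad_sim")
    }
    w <- model$introns$end - model$introns$start + 1L
    iw <- w[match(rec$intron, model$introns$intron)]
    if (any(rec$acceptor_offset > iw - 10L)) {
      abort("recursive acceptor_offset too close to the intron's 3' end",
            class = "splicestage_bad_sim")
    }
    istart <- model$introns$start[match(rec$intron, model$introns$intron)]
    iend <- model$introns$end[match(rec$intron, model$introns$intron)]
    if (config$strand == "+") {
      rec$gap_start <- istart + rec$donor_offset
      rec$gap_end <- istart + rec$acceptor_offset - 1L
    } else {
      rec$gap_end <- iend - rec$donor_offset
      rec$gap_start <- iend - rec$acceptor_offset + 1L
    }
    rec$donor <- if (config$strand == "+") rec$gap_start - 1L else
      rec$gap_end + 1L
    rec$acceptor <- if (config$strand == "+") rec$gap_end + 1L else
      rec$gap_start - 1L
    for (i in seq_len(nrow(rec))) {
      if (config$strand == "+") {
        plant(rec$gap_start[i], "GT")
        plant(rec$gap_end[i] - 1L, "AG")
      } else {
        plant(rec$gap_start[i], "CT")
        plant(rec$gap_end[i] - 1L, "AC")
      }
    }
    rec <- select(rec, "intron", "gap_start", "gap_end", "donor",
                  "acceptor", "usage")
  }

  genome <- DNAStringSet(paste(base, collapse = ""))
  names(genome) <- config$chrom
  structure(list(genome = genome, model = model, recursive = rec,
                 config = config),
            class = "sim_locus")
}

#' Write the simulated locus to FASTA and GTF
#'
#' @param locus A [simulate_locus()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector with paths `fasta` and `gtf`.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "locus.fa")
  gtf <- file.path(dir, "locus.gtf")
  writeXStringSet(locus$genome, fasta)
  write_gene_model_gtf(locus$model, gtf)
  c(fasta = fasta, gtf = gtf)
}

#' Draw a pool of molecules at mixed splicing stages
#'
#' Each molecule spans the gene and has removed a subset of introns
#' according to its stage: none (unspliced), a prefix of the configured
#' splicing order (partially spliced; snapshot semantics), or all (mature),
#' modified by per-intron retention, per-exon skipping and recursive
#' first-step gaps on intron-containing molecules.
#'
#' @param locus A [simulate_locus()] result.
#' @param n Pool size (default from the configuration).
#' @param seed Seed for the pool (default `config$seed + 1`); use different
#'   seeds for replicate samples over the same locus.
#' @param stage_mix Optional stage-mixture override (e.g. `c(1, 0, 0)` for
#'   a DNA-like unspliced control).
#' @return Tibble, one row per molecule: `molecule`, `stage`,
#'   `removed_introns` (list), `recursive_gap` (list of `c(start, end)` or
#'   `NULL`), `segments` (list: retained genomic segments with molecule
#'   coordinates), `mol_len`.
#' @export
simulate_molecules <- function(locus, n = NULL, seed = NULL,
                               stage_mix = NULL) {
  cfg <- locus$config
  n <- n %||% cfg$n_molecules
  set.seed(seed %||% (cfg$seed + 1L))
  mix <- stage_mix %||% cfg$stage_mix
  model <- locus$model
  ni <- cfg$n_introns
  span <- gene_span(model)

  stages <- sample(c("unspliced", "partial", "mature"), n, replace = TRUE,
                   prob = mix)
  intron_iv <- model$introns

  mk <- function(stage) {
    removed <- switch(stage,
      unspliced = integer(0),
      mature = seq_len(ni),
      partial = cfg$order[seq_len(sample.int(ni - 1L, 1))]
    )
    # retention: an intron can stay behind even when its turn has come
    if (length(removed) > 0) {
      keep <- runif(length(removed)) < cfg$retention[removed]
      removed <- removed[!keep]
    }
    # exon skipping needs both flanking introns out
    skipped <- integer(0)
    for (j in seq(2, cfg$n_exons - 1)) {
      if (all(c(j - 1L, j) %in% removed) && runif(1) < cfg$skip[j]) {
        skipped <- c(skipped, j)
      }
    }
    # recursive first-step gap on molecules still holding the intron
    rec_gap <- NULL
    if (!is.null(locus$recursive)) {
      for (k in seq_len(nrow(locus$recursive))) {
        ev <- locus$recursive[k, ]
        if (!(ev$intron %in% removed) && runif(1) < ev$usage) {
          rec_gap <- rbind(rec_gap, c(ev$gap_start, ev$gap_end))
        }
      }
    }
    iv <- intron_iv[match(removed, intron_iv$intron), c("start", "end")]
    if (length(skipped) > 0) {
      ex <- model$exons[match(skipped, model$exons$exon), c("start", "end")]
      iv <- bind_rows(iv, ex)
    }
    if (!is.null(rec_gap)) {
      iv <- bind_rows(iv, tibble(start = rec_gap[, 1], end = rec_gap[, 2]))
    }
    list(removed = removed, skipped = skipped, rec = rec_gap, iv = iv)
  }

  rows <- lapply(stages, mk)
  segs <- lapply(rows, function(r) {
    if (nrow(r$iv) == 0) {
      seg <- tibble(gstart = span[1], gend = span[2])
    } else {
      rem <- IRanges::reduce(IRanges(r$iv$start, r$iv$end))
      ret <- IRanges::setdiff(IRanges(span[1], span[2]), rem)
      seg <- tibble(gstart = start(ret), gend = end(ret))
    }
    w <- seg$gend - seg$gstart + 1L
    seg$mstart <- cumsum(c(1L, w[-length(w)]))
    seg$mend <- seg$mstart + w - 1L
    seg
  })

  tibble(
    molecule = seq_len(n),
    stage = stages,
    removed_introns = lapply(rows, `[[`, "removed"),
    skipped_exons = lapply(rows, `[[`, "skipped"),
    recursive_gap = lapply(rows, `[[`, "rec"),
    segments = segs,
    mol_len = vapply(segs, function(s) sum(s$gend - s$gstart + 1L),
                     integer(1))
  )
}

# map a molecule-coordinate interval [a, b] onto genomic blocks
.mol_to_blocks <- function(seg, a, b) {
  i1 <- findInterval(a, seg$mstart)
  i2 <- findInterval(b, seg$mstart)
  gs <- seg$gstart[i1:i2]
  ge <- seg$gend[i1:i2]
  gs[1] <- seg$gstart[i1] + (a - seg$mstart[i1])
  ge[length(ge)] <- seg$gstart[i2] + (b - seg$mstart[i2])
  cbind(gs, ge)
}

.blocks_to_cigar <- function(bl) {
  m <- bl[, 2] - bl[, 1] + 1L
  if (nrow(bl) == 1) return(paste0(m, "M"))
  gaps <- bl[-1, 1] - bl[-nrow(bl), 2] - 1L
  paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
         m[length(m)], "M")
}

#' Simulate paired-end reads and write a coordinate-sorted BAM
#'
#' Fragments are drawn from molecules of the pool (truncated-normal sizes,
#' uniform placement), the two outermost `read_len` stretches become the
#' mates, and molecule coordinates are mapped back to genomic blocks with
#' CIGAR `N` operations across removed regions. Proper-pair flags are set;
#' read 1 is on the forward strand. A truth table records each pair's
#' molecule and structure.
#'
#' @param locus A [simulate_locus()] result.
#' @param molecules Pool from [simulate_molecules()].
#' @param dir Output directory.
#' @param name Sample name (file stem).
#' @param n_pairs Number of pairs (default from the configuration).
#' @param seed Seed (default `config$seed + 2`).
#' @return List: `bam` (sorted, indexed), `sam`, `truth` (tibble: `qname`,
#'   `molecule`, `stage`, `removed_introns`, `has_recursive_gap`,
#'   `blocks1`, `blocks2` as "start-end;start-end" strings, `n_resampled`
#'   attribute counts fragments longer than their molecule).
#' @export
simulate_reads <- function(locus, molecules, dir, name = "sample",
                           n_pairs = NULL, seed = NULL) {
  cfg <- locus$config
  n_pairs <- n_pairs %||% cfg$n_pairs
  set.seed(seed %||% (cfg$seed + 2L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- cfg$read_len
  genome_str <- as.character(locus$genome[[1]])

  mol_idx <- sample.int(nrow(molecules), n_pairs, replace = TRUE)
  mol_len <- molecules$mol_len[mol_idx]

  frag <- as.integer(round(rnorm(n_pairs, cfg$frag_mean, cfg$frag_sd)))
  n_resampled <- 0L
  for (it in 1:50) {
    bad <- frag < cfg$frag_min | frag > mol_len
    if (!any(bad)) break
    n_resampled <- n_resampled + sum(frag > mol_len)
    frag[bad] <- as.integer(round(rnorm(sum(bad), cfg$frag_mean,
                                        cfg$frag_sd)))
  }
  frag <- pmin(pmax(frag, cfg$frag_min), mol_len)

  fs <- 1L + as.integer(floor(runif(n_pairs) * (mol_len - frag + 1L)))
  a1 <- fs; b1 <- fs + rl - 1L
  a2 <- fs + frag - rl; b2 <- fs + frag - 1L

  blocks1 <- vector("list", n_pairs)
  blocks2 <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    seg <- molecules$segments[[mol_idx[p]]]
    blocks1[[p]] <- .mol_to_blocks(seg, a1[p], b1[p])
    blocks2[[p]] <- .mol_to_blocks(seg, a2[p], b2[p])
  }

  seq_of <- function(bl) {
    paste(substring(genome_str, bl[, 1], bl[, 2]), collapse = "")
  }
  add_errors <- function(s) {
    if (cfg$error_rate <= 0) return(s)
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < cfg$error_rate
    ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }

  qname <- sprintf("%s_p%06d", name, seq_len(n_pairs))
  pos1 <- vapply(blocks1, function(b) as.integer(b[1, 1]), integer(1))
  pos2 <- vapply(blocks2, function(b) as.integer(b[1, 1]), integer(1))
  endg1 <- vapply(blocks1, function(b) as.integer(b[nrow(b), 2]), integer(1))
  endg2 <- vapply(blocks2, function(b) as.integer(b[nrow(b), 2]), integer(1))
  cig1 <- vapply(blocks1, .blocks_to_cigar, character(1))
  cig2 <- vapply(blocks2, .blocks_to_cigar, character(1))
  seq1 <- vapply(blocks1, function(b) add_errors(seq_of(b)), character(1))
  seq2 <- vapply(blocks2, function(b) add_errors(seq_of(b)), character(1))
  tlen <- as.integer(pmax(endg1, endg2) - pmin(pos1, pos2) + 1)

  line <- function(qn, flag, pos, cig, mpos, tl, sq) {
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
            qn, flag, cfg$chrom, pos, cig, mpos, tl, sq)
  }
  l1 <- line(qname, 99L, pos1, cig1, pos2, tlen, seq1)
  l2 <- line(qname, 147L, pos2, cig2, pos1, -tlen, seq2)
  body <- c(l1, l2)[order(c(pos1, pos2))]

  sam <- file.path(dir, paste0(name, ".sam"))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom,
                      Biostrings::width(locus$genome)[1]))
  writeLines(c(header, body), sam)
  bam <- asBam(sam, file.path(dir, name), overwrite = TRUE,
               indexDestination = TRUE)

  fmt_blocks <- function(bl) paste(bl[, 1], bl[, 2], sep = "-",
                                   collapse = ";")
  truth <- tibble(
    qname = qname,
    molecule = mol_idx,
    stage = molecules$stage[mol_idx],
    removed_introns = vapply(molecules$removed_introns[mol_idx],
                             function(x) paste(x, collapse = ","),
                             character(1)),
    has_recursive_gap = !vapply(molecules$recursive_gap[mol_idx], is.null,
                                logical(1)),
    blocks1 = vapply(blocks1, fmt_blocks, character(1)),
    blocks2 = vapply(blocks2, fmt_blocks, character(1))
  )
  attr(truth, "n_resampled") <- n_resampled
  list(bam = bam, sam = sam, truth = truth)
}

#' Simulate one sample over a locus
#'
#' Convenience wrapper: molecule pool + reads, with per-sample seeding so
#' replicate samples share the locus but not the noise.
#'
#' @param locus A [simulate_locus()] result.
#' @param dir Output directory.
#' @param name Sample name.
#' @param seed Sample seed (defaults to the configuration seed).
#' @param stage_mix Optional stage-mixture override (see
#'   [simulate_molecules()]); `c(1, 0, 0)` gives an unspliced, DNA-like
#'   control with no split reads.
#' @param n_pairs Optional pair-count override.
#' @return As [simulate_reads()], plus `molecules`.
#' @export
simulate_sample <- function(locus, dir, name = "sample",
                            seed = locus$config$seed,
                            stage_mix = NULL, n_pairs = NULL) {
  mol <- simulate_molecules(locus, seed = seed * 1000L + 1L,
                            stage_mix = stage_mix)
  res <- simulate_reads(locus, mol, dir, name = name, n_pairs = n_pairs,
                        seed = seed * 1000L + 2L)
  res$molecules <- mol
  res
}
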