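# Shared fixtures: a toy three-exon gene, a hand-rolled SAM/BAM writer for
# exactly specified read pairs, and an independent brute-force classifier
# used as the oracle against the pipeline's vectorized path.

toy_model <- function(strand = "+") {
  gene_model("G", "chr1", strand,
             data.frame(start = c(101, 301, 501),
                        end   = c(200, 400, 600)))
}

# blocks: list of matrices/data.frames with columns start, end
blocks_cigar <- function(bl) {
  bl <- as.matrix(bl)
  m <- bl[, 2] - bl[, 1] + 1
  if (nrow(bl) == 1) return(paste0(m, "M"))
  gaps <- bl[-1, 1] - bl[-nrow(bl), 2] - 1
  paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
         m[length(m)], "M")
}

# pairs: list of list(blocks1 =, blocks2 =); writes a sorted, indexed BAM
make_pair_bam <- function(pairs, chrom = "chr1", chrlen = 10000,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  recs <- purrr::imap(pairs, function(p, i) {
    b1 <- as.matrix(p$blocks1); b2 <- as.matrix(p$blocks2)
    qn <- sprintf("pair%04d", i)
    w1 <- sum(b1[, 2] - b1[, 1] + 1); w2 <- sum(b2[, 2] - b2[, 1] + 1)
    c(sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
              qn, chrom, b1[1, 1], blocks_cigar(b1), b2[1, 1],
              max(b1[, 2], b2[, 2]) - min(b1[, 1], b2[, 1]) + 1,
              strrep("A", w1)),
      sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
              qn, chrom, b2[1, 1], blocks_cigar(b2), b1[1, 1],
              -(max(b1[, 2], b2[, 2]) - min(b1[, 1], b2[, 1]) + 1),
              strrep("A", w2)))
  })
  lines <- unlist(recs)
  pos <- as.integer(sub("^\\S+\t\\d+\t\\S+\t(\\d+)\t.*$", "\\1", lines))
  sam <- file.path(dir, "handmade.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen),
               lines[order(pos)]), sam)
  Rsamtools::asBam(sam, file.path(dir, "handmade"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# ---- independent oracle (plain, scalar logic; no package internals) ----

oracle_label <- function(bl, model) {
  bl <- as.matrix(bl)
  sp <- c(min(model$exons$start), max(model$exons$end))
  if (any(bl[, 1] < sp[1]) || any(bl[, 2] > sp[2])) return("outside")
  feat_of <- function(p) {
    for (i in seq_len(nrow(model$exons))) {
      if (p >= model$exons$start[i] && p <= model$exons$end[i]) {
        return(c("exon", model$exons$exon[i]))
      }
    }
    for (i in seq_len(nrow(model$introns))) {
      if (p >= model$introns$start[i] && p <= model$introns$end[i]) {
        return(c("intron", model$introns$intron[i]))
      }
    }
    c("none", NA)
  }
  if (nrow(bl) == 1) {
    f1 <- feat_of(bl[1, 1]); f2 <- feat_of(bl[1, 2])
    if (identical(f1, f2)) {
      return(if (f1[1] == "exon") "ex" else "int")
    }
    return("ex-int")
  }
  # split end: every gap must equal an annotated intron, all blocks exonic
  for (k in seq_len(nrow(bl) - 1)) {
    gs <- bl[k, 2] + 1; ge <- bl[k + 1, 1] - 1
    hit <- any(model$introns$start == gs & model$introns$end == ge)
    if (!hit) return("other")
  }
  for (k in seq_len(nrow(bl))) {
    f1 <- feat_of(bl[k, 1]); f2 <- feat_of(bl[k, 2])
    if (!(identical(f1, f2) && f1[1] == "exon")) return("other")
  }
  "ex-ex"
}

oracle_feat_idx <- function(bl, model) {
  # index of the single feature containing a contiguous end, else NA
  bl <- as.matrix(bl)
  if (nrow(bl) != 1) return(NA_integer_)
  ft <- rbind(
    data.frame(kind = "exon", index = model$exons$exon,
               start = model$exons$start, end = model$exons$end),
    data.frame(kind = "intron", index = model$introns$intron,
               start = model$introns$start, end = model$introns$end)
  )
  i <- which(ft$start <= bl[1, 1] & ft$end >= bl[1, 2])
  if (length(i) == 1) ft$index[i] else NA_integer_
}

oracle_category <- function(lab1, lab2, dist, same_feature = FALSE,
                            expected = 650) {
  labs <- sort(c(lab1, lab2))
  if (any(!labs %in% c("int", "ex", "ex-ex", "ex-int")) || is.na(dist)) {
    return("unclassified")
  }
  key <- paste(labs, collapse = "|")
  within <- dist < expected
  if (key == "ex-int|int" || key == "ex|ex-int" ||
      key == "ex-int|ex-int") return("pre")
  if (key == "int|int") return(if (within) "pre" else "intermediate")
  if (key == "ex|int") return(if (within) "pre" else "intermediate")
  if (key == "ex-ex|int" || key == "ex-ex|ex-int") return("intermediate")
  if (key == "ex-ex|ex-ex" || key == "ex|ex-ex") return("post")
  if (key == "ex|ex") return(if (same_feature) "unknown" else "post")
  stop("unreachable: ", key)
}

parse_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

# oracle classification of a simulated truth table (blocks -> labels ->
# category), fully independent of the pipeline path
oracle_classify_truth <- function(truth, model, expected = 650) {
  vapply(seq_len(nrow(truth)), function(i) {
    b1 <- parse_blocks(truth$blocks1[i])
    b2 <- parse_blocks(truth$blocks2[i])
    l1 <- oracle_label(b1, model)
    l2 <- oracle_label(b2, model)
    d <- max(0, max(min(b1[, 1]), min(b2[, 1])) -
               min(max(b1[, 2]), max(b2[, 2])) - 1)
    sf <- !is.na(oracle_feat_idx(b1, model)) &&
      identical(oracle_feat_idx(b1, model), oracle_feat_idx(b2, model)) &&
      l1 %in% c("ex", "int") && l1 == l2
    oracle_category(l1, l2, d, sf, expected)
  }, character(1))
}
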