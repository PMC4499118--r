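test_that("the locus is deterministic under its seed", {
  cfg <- sim_config(seed = 7)
  a <- simulate_locus(cfg)
  b <- simulate_locus(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$model$exons, b$model$exons)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  s1 <- simulate_sample(a, dir1, "s", seed = 3, n_pairs = 300)
  s2 <- simulate_sample(b, dir2, "s", seed = 3, n_pairs = 300)
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  expect_identical(s1$truth, s2$truth)
})

test_that("canonical motifs are planted at annotated and recursive sites", {
  for (strand in c("+", "-")) {
    cfg <- sim_config(seed = 13, strand = strand,
                      recursive = data.frame(intron = 3, donor_offset = 0,
                                             acceptor_offset = 120,
                                             usage = 0.3))
    loc <- simulate_locus(cfg)
    seq <- loc$genome[[1]]
    get <- function(s, e) {
      x <- Biostrings::subseq(seq, s, e)
      if (strand == "-") as.character(Biostrings::reverseComplement(x))
      else as.character(x)
    }
    for (i in seq_len(nrow(loc$model$introns))) {
      s <- loc$model$introns$start[i]; e <- loc$model$introns$end[i]
      if (strand == "+") {
        expect_equal(get(s, s + 1), "GT")
        expect_equal(get(e - 1, e), "AG")
      } else {
        expect_equal(get(e - 1, e), "GT")   # transcription 5' end
        expect_equal(get(s, s + 1), "AG")
      }
    }
    # planted recursive acceptor preceded by AG (in transcript orientation)
    rec <- loc$recursive
    if (strand == "+") {
      expect_equal(get(rec$gap_end - 1, rec$gap_end), "AG")
      expect_equal(get(rec$gap_start, rec$gap_start + 1), "GT")
    } else {
      expect_equal(get(rec$gap_start, rec$gap_start + 1), "AG")
      expect_equal(get(rec$gap_end - 1, rec$gap_end), "GT")
    }
  }
})

test_that("molecule structures respect stage, order and recursive usage", {
  cfg <- sim_config(seed = 17, n_molecules = 2000,
                    order = c(1L, 2L, 4L, 3L, 5L, 6L),
                    recursive = data.frame(intron = 5, donor_offset = 0,
                                           acceptor_offset = 200,
                                           usage = 0.3))
  loc <- simulate_locus(cfg)
  mol <- simulate_molecules(loc, seed = 2)

  all_intr <- mol[mol$stage == "unspliced", ]
  expect_true(all(lengths(all_intr$removed_introns) == 0))
  mat <- mol[mol$stage == "mature", ]
  expect_true(all(lengths(mat$removed_introns) == 6))

  # order override: intron 3 never removed while intron 4 is present
  bad <- vapply(mol$removed_introns,
                function(r) (3L %in% r) && !(4L %in% r), logical(1))
  expect_false(any(bad))

  # recursive usage ~ 0.3 of intron-5-containing molecules (binomial CI)
  holds5 <- vapply(mol$removed_introns, function(r) !(5L %in% r),
                   logical(1))
  used <- vapply(mol$recursive_gap, Negate(is.null), logical(1))
  phat <- mean(used[holds5])
  n <- sum(holds5)
  ci <- 0.3 + c(-4, 4) * sqrt(0.3 * 0.7 / n)
  expect_gt(phat, ci[1]); expect_lt(phat, ci[2])
  expect_false(any(used[!holds5]))
})

test_that("emitted BAM is valid, paired and matches its truth table", {
  cfg <- sim_config(seed = 19, n_pairs = 500, n_molecules = 200)
  loc <- simulate_locus(cfg)
  dir <- withr::local_tempdir()
  s <- simulate_sample(loc, dir, "v", seed = 4)

  expect_true(file.exists(s$bam))
  expect_true(file.exists(paste0(s$bam, ".bai")))
  expect_equal(nrow(s$truth), 500L)

  gal <- read_gene_alignments(s$bam)
  expect_equal(length(gal), 1000L)
  expect_false(is.unsorted(GenomicAlignments::start(gal)))

  # CIGAR blocks reproduce the truth blocks for every end
  ends <- label_ends(gal, loc$model)
  e1 <- ends[ends$mate == 1L, ]
  blocks_str <- function(g) {
    irl <- GenomicAlignments::extractAlignmentRangesOnReference(
      GenomicAlignments::cigar(g), pos = GenomicAlignments::start(g),
      drop.D.ranges = FALSE)
    vapply(as.list(irl), function(ir) {
      paste(IRanges::start(ir), IRanges::end(ir), sep = "-", collapse = ";")
    }, character(1))
  }
  g1 <- gal[bitwAnd(S4Vectors::mcols(gal)$flag, 64L) > 0L]
  got <- blocks_str(g1)[match(s$truth$qname, names(g1))]
  expect_equal(got, s$truth$blocks1)

  # a mature-molecule pair spanning a junction is labeled ex-ex
  mature_q <- s$truth$qname[s$truth$stage == "mature"]
  exex <- ends$label[ends$qname %in% mature_q & ends$label == "ex-ex"]
  expect_true(length(exex) > 0)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(stage_mix = c(0.5, 0.2, 0.2)),
               class = "splicestage_bad_sim")
  expect_error(sim_config(frag_min = 50, read_len = 100),
               class = "splicestage_bad_sim")
  expect_error(sim_config(order = c(1L, 1L, 2L, 3L, 4L, 5L)),
               class = "splicestage_bad_sim")
  expect_error(sim_config(recursive = data.frame(intron = 1,
                                                 acceptor_offset = 3,
                                                 usage = 0.5)),
               class = "splicestage_bad_sim")
  expect_error(
    simulate_locus(sim_config(recursive = data.frame(intron = 99,
                                                     acceptor_offset = 100,
                                                     usage = 0.5))),
    class = "splicestage_bad_sim")
})

test_that("locus FASTA/GTF round-trip through the standard readers", {
  cfg <- sim_config(seed = 23)
  loc <- simulate_locus(cfg)
  dir <- withr::local_tempdir()
  paths <- write_locus(loc, dir)
  genome <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(as.character(genome[[1]]), as.character(loc$genome[[1]]))
  back <- read_gene_models(paths["gtf"])[["simGene"]]
  expect_equal(back$exons, loc$model$exons)
  expect_equal(back$introns, loc$model$introns)
})
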