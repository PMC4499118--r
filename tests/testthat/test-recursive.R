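test_that("gap extraction drops annotated junctions, keeps novel splits", {
  gm <- toy_model("+")
  pairs <- list(
    list(blocks1 = rbind(c(190, 200), c(301, 310)),   # annotated: dropped
         blocks2 = cbind(700, 750)),
    list(blocks1 = rbind(c(190, 200), c(260, 270)),   # intra-intronic
         blocks2 = cbind(700, 750)),
    list(blocks1 = cbind(150, 190), blocks2 = cbind(700, 750))  # unsplit
  )
  bam <- make_pair_bam(pairs)
  gaps <- extract_gaps(bam, gm)
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$gap_start, 201L)
  expect_equal(gaps$gap_end, 259L)
  expect_equal(gaps$donor, 200L)
  expect_equal(gaps$acceptor, 260L)
})

test_that("gap peaks follow the derivative convention with exclusions", {
  gaps3 <- tibble::tibble(gap_start = rep(201L, 3), gap_end = rep(259L, 3))
  pk <- gap_peaks(gaps3)
  expect_equal(pk$pos, c(201L, 260L))
  expect_equal(pk$sign, c(1L, -1L))
  expect_equal(pk$magnitude, c(3L, 3L))

  # position 260 both closes one gap and opens another: excluded
  gaps2 <- tibble::tibble(gap_start = c(201L, 260L), gap_end = c(259L, 300L))
  pk2 <- gap_peaks(gaps2)
  expect_false(260L %in% pk2$pos)
  expect_equal(pk2$pos, c(201L, 301L))

  expect_equal(nrow(gap_peaks(tibble::tibble(gap_start = integer(),
                                             gap_end = integer()))), 0L)
})

test_that("gap conservation: positive and negative magnitudes balance", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    gs <- sample(1000:5000, n, replace = TRUE)
    gaps <- tibble::tibble(gap_start = gs,
                           gap_end = gs + sample(30:400, n, replace = TRUE))
    pk <- gap_peaks(gaps)
    # before the both-start-and-end exclusion the sums equal the gap count
    starts <- table(gaps$gap_start); ends <- table(gaps$gap_end + 1L)
    expect_equal(sum(starts), nrow(gaps))
    expect_equal(sum(ends), nrow(gaps))
    # after exclusion both sides lose the same excluded positions
    both <- intersect(names(starts), names(ends))
    expect_equal(sum(pk$magnitude[pk$sign == 1]),
                 nrow(gaps) - sum(starts[both]))
    expect_equal(attr(pk, "n_gaps"), nrow(gaps))
  }
})

test_that("inverted coverage integrates the gaps", {
  gaps <- tibble::tibble(gap_start = c(201L, 201L, 210L),
                         gap_end = c(259L, 259L, 230L))
  ic <- inverted_coverage(gaps)
  expect_equal(ic$inverted_coverage[ic$pos == 205], 2L)
  expect_equal(ic$inverted_coverage[ic$pos == 215], 3L)
  expect_equal(ic$inverted_coverage[ic$pos == 259], 2L)
  # derivative of the inverted coverage equals the signed peaks
  d <- diff(c(0L, ic$inverted_coverage))
  expect_equal(ic$pos[d > 0], c(201L, 210L))
})

test_that("consensus requires same-sign support and sums magnitudes", {
  mk <- function(pos, sign, mag) {
    structure(tibble::tibble(pos = pos, sign = sign, magnitude = mag),
              class = c("gap_peaks", "tbl_df", "tbl", "data.frame"))
  }
  pk <- list(s1 = mk(201L, 1L, 3L), s2 = mk(201L, 1L, 2L),
             s3 = mk(201L, 1L, 4L))
  cons <- consensus_peaks(pk, min_samples = 3)
  expect_equal(cons$magnitude, 9L)
  expect_equal(cons$n_samples, 3L)

  pk2 <- list(s1 = mk(201L, 1L, 3L), s2 = mk(201L, 1L, 2L),
              s3 = mk(999L, 1L, 4L))
  expect_equal(nrow(consensus_peaks(pk2, min_samples = 3)), 0L)

  # opposite signs at one position never merge
  pk3 <- list(s1 = mk(201L, 1L, 3L), s2 = mk(201L, -1L, 3L))
  expect_equal(nrow(consensus_peaks(pk3, min_samples = 2)), 0L)

  # singleton peaks are excluded by the per-sample magnitude floor
  pk4 <- list(s1 = mk(201L, 1L, 1L), s2 = mk(201L, 1L, 1L))
  expect_equal(nrow(consensus_peaks(pk4, min_samples = 2)), 0L)
  expect_equal(nrow(consensus_peaks(pk4, min_samples = 2,
                                    min_magnitude = 1)), 1L)

  expect_error(consensus_peaks(pk, min_samples = 5),
               class = "splicestage_min_samples")
})

test_that("wiggle round trip preserves position, sign and magnitude", {
  pk <- gap_peaks(tibble::tibble(gap_start = c(201L, 201L, 350L),
                                 gap_end = c(259L, 259L, 420L)))
  path <- withr::local_tempfile(fileext = ".wig")
  write_peaks_wig(pk, path, "chr1", "t")
  back <- read_peaks_wig(path)
  expect_equal(back$pos, pk$pos)
  expect_equal(back$sign, pk$sign)
  expect_equal(back$magnitude, pk$magnitude)
  expect_equal(attr(back, "chrom"), "chr1")
  # byte stability
  path2 <- withr::local_tempfile(fileext = ".wig")
  write_peaks_wig(back, path2, "chr1", "t")
  expect_identical(readLines(path), readLines(path2))
})

test_that("junction matrix tallies consensus-supported splits with annotation", {
  gm <- toy_model("+")
  # 5 reads split from the annotated donor (exon 1 end) to an
  # intra-intronic acceptor at 260, plus 3 reads split wholly inside
  # intron 2 (both sites novel)
  mk5 <- function() list(blocks1 = rbind(c(190, 200), c(260, 270)),
                         blocks2 = cbind(700, 750))
  mk_inner <- function() list(blocks1 = rbind(c(410, 420), c(470, 480)),
                              blocks2 = cbind(700, 750))
  bam <- make_pair_bam(c(replicate(5, mk5(), simplify = FALSE),
                         replicate(3, mk_inner(), simplify = FALSE)))
  gaps <- list(s1 = extract_gaps(bam, gm))
  cons <- consensus_peaks(lapply(gaps, gap_peaks), min_samples = 1)
  jm <- junction_matrix(gaps, cons, gm)
  expect_equal(nrow(jm), 2L)
  gray <- jm[jm$donor == 200, ]
  expect_equal(gray$count, 5L)
  expect_true(gray$donor_annotated)
  expect_false(gray$acceptor_annotated)
  white <- jm[jm$donor == 420, ]
  expect_equal(white$count, 3L)
  expect_false(white$donor_annotated)

  m <- as.matrix(jm)
  expect_equal(m["260", "200"], 5L)
  expect_equal(m["470", "420"], 3L)
  expect_equal(sum(m), 8L)

  ev <- classify_events(jm, gm)
  expect_equal(ev$type[ev$donor == 200], "5prime_recursive")
  expect_equal(ev$type[ev$donor == 420], "inner")
})

test_that("events sharing an annotated site group into multi-step chains", {
  gm <- toy_model("+")
  jm <- structure(
    tibble::tibble(donor = c(230L, 250L, 420L),
                   acceptor = c(301L, 301L, 470L),
                   count = c(4L, 6L, 3L), n_samples = c(2L, 2L, 2L),
                   donor_annotated = c(FALSE, FALSE, FALSE),
                   acceptor_annotated = c(TRUE, TRUE, FALSE)),
    class = c("junction_matrix", "tbl_df", "tbl", "data.frame"))
  ev <- classify_events(jm, gm)
  expect_equal(ev$type, c("3prime_recursive", "3prime_recursive", "inner"))
  expect_equal(ev$chain_group[1], ev$chain_group[2])
  expect_true(is.na(ev$chain_group[3]))
})

test_that("motif analysis recovers planted GT/AG on both strands", {
  for (strand in c("+", "-")) {
    cfg <- sim_config(seed = 51, strand = strand,
                      recursive = data.frame(intron = 2, donor_offset = 0,
                                             acceptor_offset = 150,
                                             usage = 0.5),
                      n_pairs = 800, n_molecules = 300)
    loc <- simulate_locus(cfg)
    jm <- structure(
      tibble::tibble(donor = loc$recursive$donor,
                     acceptor = loc$recursive$acceptor,
                     count = 5L, n_samples = 4L,
                     donor_annotated = loc$recursive$donor %in%
                       loc$model$junctions$donor,
                     acceptor_annotated = FALSE),
      class = c("junction_matrix", "tbl_df", "tbl", "data.frame"))
    ma <- motif_analysis(jm, loc$genome, loc$model)
    expect_equal(ma$events$donor_motif, "GT")
    expect_equal(ma$events$acceptor_motif, "AG")
    expect_true(all(ma$events$canonical_novel_site))
    expect_equal(ma$summary$pct_canonical, 100)
  }
})

test_that("motif percentages count canonical novel sites only", {
  # synthetic contig with known dinucleotides; 10 events with one novel
  # acceptor each: 8 preceded by AG, 2 not
  base <- rep("A", 3000)
  gm <- gene_model("G", "ctg", "+",
                   data.frame(start = c(101, 1201), end = c(1100, 2100)))
  ev_pos <- seq(1150, by = 60, length.out = 10)  # novel acceptors in intron 1
  for (k in seq_along(ev_pos)) {
    motif <- if (k <= 8) c("A", "G") else c("C", "C")
    base[(ev_pos[k] - 2):(ev_pos[k] - 1)] <- motif
  }
  base[1101:1102] <- c("G", "T")  # canonical donor at the annotated site
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- "ctg"
  jm <- structure(
    tibble::tibble(donor = 1100L, acceptor = as.integer(ev_pos),
                   count = 3L, n_samples = 4L,
                   donor_annotated = TRUE, acceptor_annotated = FALSE),
    class = c("junction_matrix", "tbl_df", "tbl", "data.frame"))
  ma <- motif_analysis(jm, genome, gm)
  expect_equal(ma$summary$pct_canonical, 80)
  expect_equal(sum(ma$events$canonical_acceptor), 8L)
})

test_that("novel-exon flagging needs elevated coverage between peaks", {
  gm <- toy_model("+")
  # cryptic exon [240, 259] inside intron 1: split reads flank it and
  # deep reads cover it; background intron coverage is low
  flank_in <- function() list(blocks1 = rbind(c(190, 200), c(240, 250)),
                              blocks2 = cbind(700, 750))
  flank_out <- function() list(blocks1 = rbind(c(250, 259), c(301, 310)),
                               blocks2 = cbind(700, 750))
  deep <- function() list(blocks1 = cbind(240, 259),
                          blocks2 = cbind(240, 259))
  bg <- function() list(blocks1 = cbind(205, 300), blocks2 = cbind(205, 300))
  bam <- make_pair_bam(c(replicate(3, flank_in(), simplify = FALSE),
                         replicate(3, flank_out(), simplify = FALSE),
                         replicate(10, deep(), simplify = FALSE),
                         list(bg())))
  gaps <- extract_gaps(bam, gm)
  cons <- consensus_peaks(list(s1 = gap_peaks(gaps)), min_samples = 1)
  # the gap [201,239] closes at 240 (-peak) and the gap [260,300] opens at
  # 260 (+peak): candidate interval [240, 259]
  novel <- flag_novel_exons(cons, bam, gm, k = 2)
  hit <- novel[novel$start == 240 & novel$end == 259, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$flagged)

  ev <- classify_events(junction_matrix(list(s1 = gaps), cons, gm), gm)
  kept <- exclude_novel_exon_events(ev, novel, gm)
  expect_false(any(kept$acceptor == 240 | kept$donor == 259))

  # background-coverage interval is not flagged
  novel_bg <- flag_novel_exons(cons, bam, gm, k = 100)
  expect_false(any(novel_bg$flagged))
})
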