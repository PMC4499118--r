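test_that("end labels follow the mapping-location rules", {
  gm <- toy_model("+")
  expect_equal(label_end(data.frame(start = 150, end = 160), gm), "ex")
  expect_equal(label_end(data.frame(start = 250, end = 260), gm), "int")
  expect_equal(label_end(data.frame(start = 195, end = 205), gm), "ex-int")
  expect_equal(label_end(data.frame(start = c(190, 301),
                                    end = c(200, 310)), gm), "ex-ex")
  # split whose gap is not an annotated intron
  expect_equal(label_end(data.frame(start = c(190, 320),
                                    end = c(200, 330)), gm), "other")
  expect_equal(label_end(data.frame(start = 1, end = 50), gm), "outside")
  # a split across both junctions is still ex-ex
  expect_equal(label_end(data.frame(start = c(190, 301, 501),
                                    end = c(200, 400, 510)), gm), "ex-ex")
  # exonic flanks required: one flank dipping into the intron is not ex-ex
  expect_equal(label_end(data.frame(start = c(190, 301),
                                    end = c(205, 310)), gm), "other")
})

test_that("mapping distance is the clamped inner distance", {
  expect_equal(mapping_distance(data.frame(start = 100, end = 199),
                                data.frame(start = 300, end = 399)), 100)
  expect_equal(mapping_distance(data.frame(start = 100, end = 250),
                                data.frame(start = 200, end = 350)), 0)
  expect_equal(mapping_distance(data.frame(start = 100, end = 200),
                                data.frame(start = 201, end = 300)), 0)
  # order of arguments is irrelevant
  expect_equal(mapping_distance(data.frame(start = 300, end = 399),
                                data.frame(start = 100, end = 199)), 100)
})

test_that("pair classification matches the documented decision table", {
  expect_equal(classify_pair("ex-int", "ex-ex", 100)$category, "intermediate")
  expect_equal(classify_pair("ex", "ex", 10, same_feature = TRUE)$category,
               "unknown")
  expect_equal(classify_pair("int", "int", 80, same_feature = TRUE)$category,
               "pre")
  r <- classify_pair("int", "int", 900, same_feature = FALSE)
  expect_equal(r$category, "intermediate")
  expect_true(r$large)
  expect_equal(classify_pair("int", "ex", 700)$category, "intermediate")
  expect_equal(classify_pair("ex", "ex", 100, same_feature = FALSE)$category,
               "post")
  expect_equal(classify_pair("other", "ex", 100)$category, "unclassified")
  expect_equal(classify_pair("ex", "ex", NA, same_feature = TRUE)$category,
               "unclassified")
})

test_that("the decision table is total and symmetric", {
  labs <- c("int", "ex", "ex-ex", "ex-int")
  dt <- decision_table()
  for (i in seq_along(labs)) {
    for (j in i:length(labs)) {
      for (within in c(TRUE, FALSE)) {
        sf_opts <- if (labs[i] == labs[j] && labs[i] %in% c("ex", "int")) {
          c(TRUE, FALSE)
        } else {
          NA
        }
        for (sf in sf_opts) {
          d <- if (within) 100 else 900
          got <- classify_pair(labs[i], labs[j], d, same_feature = sf)$category
          # label order must not matter
          expect_equal(classify_pair(labs[j], labs[i], d,
                                     same_feature = sf)$category, got)
          expect_true(got %in% c("pre", "intermediate", "post", "unknown"))
          # agree with the published table row
          row <- dt[dt$label1 == min(labs[i], labs[j]) |
                      dt$label1 == labs[i] | dt$label1 == labs[j], ]
          row <- row[(row$label1 == labs[i] & row$label2 == labs[j]) |
                       (row$label1 == labs[j] & row$label2 == labs[i]), ]
          row <- row[is.na(row$within) | row$within == within, ]
          if (!all(is.na(row$same_feature))) {
            row <- row[row$same_feature %in% sf, ]
          }
          expect_equal(nrow(row), 1L)
          expect_equal(got, row$category)
        }
      }
    }
  }
})

test_that("raising the distance threshold never demotes a within-pair", {
  # the 'outside' set shrinks as the threshold grows, so a pair classified
  # pre via the within branch stays pre
  for (d in c(0, 100, 400, 649, 651, 1000)) {
    for (thr in c(500, 650, 800, 1200)) {
      c1 <- classify_pair("int", "ex", d, expected_distance = thr)$category
      c2 <- classify_pair("int", "ex", d,
                          expected_distance = thr + 200)$category
      if (c1 == "pre") expect_equal(c2, "pre")
    }
  }
})

test_that("classify_sample pairs mates and counts every pair once", {
  gm <- toy_model("+")
  pairs <- list(
    list(blocks1 = cbind(150, 190), blocks2 = cbind(520, 560)),   # post
    list(blocks1 = cbind(210, 250), blocks2 = cbind(260, 290)),   # pre
    list(blocks1 = cbind(110, 150), blocks2 = cbind(160, 195)),   # unknown
    list(blocks1 = cbind(210, 250),
         blocks2 = rbind(c(390, 400), c(501, 510))),              # intermediate
    list(blocks1 = cbind(150, 190),
         blocks2 = rbind(c(190, 200), c(320, 330)))               # other -> unclassified
  )
  bam <- make_pair_bam(pairs)
  cls <- classify_sample(bam, gm)
  expect_equal(cls$n_pairs, 5L)
  got <- cls$pairs[order(cls$pairs$qname), ]
  expect_equal(got$category,
               c("post", "pre", "unknown", "intermediate", "unclassified"))
  expect_equal(sum(cls$summary$count), cls$n_pairs)
  expect_equal(sum(cls$summary$fraction), 1)
})

test_that("pure stage mixtures classify as their stage implies", {
  cfg <- sim_config(n_pairs = 400, n_molecules = 200, seed = 11)
  loc <- simulate_locus(cfg)
  dir <- withr::local_tempdir()

  mat <- simulate_sample(loc, dir, "mature", seed = 1,
                         stage_mix = c(0, 0, 1))
  cls_m <- classify_sample(mat$bam, loc$model)
  s <- cls_m$summary
  expect_equal(s$count[s$category == "pre"], 0L)

  uns <- simulate_sample(loc, dir, "unspliced", seed = 2,
                         stage_mix = c(1, 0, 0))
  cls_u <- classify_sample(uns$bam, loc$model)
  s <- cls_u$summary
  expect_equal(s$count[s$category == "post"], 0L)
})

test_that("pipeline categories equal the molecule-truth oracle", {
  cfg <- sim_config(n_pairs = 1500, n_molecules = 400, seed = 5,
                    stage_mix = c(unspliced = 0.6, partial = 0,
                                  mature = 0.4))
  loc <- simulate_locus(cfg)
  dir <- withr::local_tempdir()
  s <- simulate_sample(loc, dir, "mix", seed = 3)
  cls <- classify_sample(s$bam, loc$model)
  got <- cls$pairs$category[match(s$truth$qname, cls$pairs$qname)]
  want <- oracle_classify_truth(s$truth, loc$model)
  expect_equal(got, want)
})
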