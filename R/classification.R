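#' The splicing-stage decision table
#'
#' A read pair's splicing-stage category is a pure function of the two end
#' labels, whether its mapping distance falls within (`W`) or outside (`O`)
#' the expected fragment range, and -- for `(int,int)` and `(ex,ex)` pairs --
#' whether both ends hit the same feature. The full table:
#'
#' * `(ex-int, int)`, `(ex-int, ex)`, `(ex-int, ex-int)`: **pre**, any
#'   distance (ends partially or fully mapped to intronic sequence);
#' * `(int, int)` within: **pre** (same or different introns); outside:
#'   **intermediate**;
#' * `(int, ex)` within: **pre**; outside: **intermediate** (distant exon);
#' * `(int, ex-ex)` and `(ex-int, ex-ex)`: **intermediate**, any distance
#'   (one end carries pre-mRNA, the other mature-mRNA evidence);
#' * `(ex-ex, ex-ex)` and `(ex-ex, ex)`: **post**, any distance;
#' * `(ex, ex)` same exon: **unknown** (exons are present at every stage);
#'   different exons: **post**.
#'
#' Pairs containing an `other` or `outside` end, or with undefined distance,
#' are `unclassified`.
#'
#' @return Tibble enumerating every unordered label pair x distance bucket
#'   (x same/different feature where it matters) with its category.
#' @export
decision_table <- function() {
  tribble <- tibble::tribble
  tribble(
    ~label1,  ~label2,  ~same_feature, ~within, ~category,
    "int",    "int",    NA,            TRUE,    "pre",
    "int",    "int",    NA,            FALSE,   "intermediate",
    "int",    "ex",     NA,            TRUE,    "pre",
    "int",    "ex",     NA,            FALSE,   "intermediate",
    "int",    "ex-ex",  NA,            NA,      "intermediate",
    "int",    "ex-int", NA,            NA,      "pre",
    "ex",     "ex",     TRUE,          NA,      "unknown",
    "ex",     "ex",     FALSE,         NA,      "post",
    "ex",     "ex-ex",  NA,            NA,      "post",
    "ex",     "ex-int", NA,            NA,      "pre",
    "ex-ex",  "ex-ex",  NA,            NA,      "post",
    "ex-ex",  "ex-int", NA,            NA,      "intermediate",
    "ex-int", "ex-int", NA,            NA,      "pre"
  )
}

.label_order <- c("int", "ex", "ex-ex", "ex-int")

#' Classify read pairs by splicing stage
#'
#' Applies [decision_table()] to vectors of end labels and mapping
#' distances. Distances below `expected_distance` count as "within" the
#' expected fragment range; the `large` flag (independent of category
#' membership) marks pairs at or above `large_threshold`.
#'
#' @param label1,label2 End labels (see [label_ends()]).
#' @param distance Inner mapping distances (bases); `NA` for pairs with ends
#'   on different chromosomes.
#' @param same_feature Logical: both ends fully inside the same exon (for
#'   `(ex,ex)` pairs) or same intron. Only consulted for `(ex,ex)`.
#' @param expected_distance Within/outside cutoff in bases. The operational
#'   value used on real nuclear RNA-seq is 650 (the prose expectation is
#'   "around 500"); default 650.
#' @param large_threshold Distance at or above which a pair is flagged
#'   `large`; default 650.
#' @return Tibble with `category` (`pre`, `intermediate`, `post`, `unknown`,
#'   `unclassified`) and `large`.
#' @export
#' @examples
#' classify_pair("ex-int", "ex-ex", 100)  # intermediate
#' classify_pair("ex", "ex", 10, same_feature = TRUE)  # unknown
classify_pair <- function(label1, label2, distance,
                          same_feature = NA,
                          expected_distance = 650,
                          large_threshold = 650) {
  n <- max(length(label1), length(label2), length(distance))
  label1 <- rep_len(label1, n); label2 <- rep_len(label2, n)
  distance <- rep_len(distance, n)
  same_feature <- rep_len(same_feature, n)

  ok <- label1 %in% .label_order & label2 %in% .label_order & !is.na(distance)
  # canonical unordered form
  a <- pmin(match(label1, .label_order), match(label2, .label_order))
  b <- pmax(match(label1, .label_order), match(label2, .label_order))
  l1 <- .label_order[a]; l2 <- .label_order[b]
  within <- distance < expected_distance

  cat <- rep("unclassified", n)
  idx <- function(x, y) ok & l1 == x & l2 == y
  cat[idx("int", "int") & within] <- "pre"
  cat[idx("int", "int") & !within] <- "intermediate"
  cat[idx("int", "ex") & within] <- "pre"
  cat[idx("int", "ex") & !within] <- "intermediate"
  cat[idx("int", "ex-ex")] <- "intermediate"
  cat[idx("int", "ex-int")] <- "pre"
  cat[idx("ex", "ex") & same_feature %in% TRUE] <- "unknown"
  cat[idx("ex", "ex") & same_feature %in% FALSE] <- "post"
  cat[idx("ex", "ex-ex")] <- "post"
  cat[idx("ex", "ex-int")] <- "pre"
  cat[idx("ex-ex", "ex-ex")] <- "post"
  cat[idx("ex-ex", "ex-int")] <- "intermediate"
  cat[idx("ex-int", "ex-int")] <- "pre"

  tibble(category = cat,
         large = !is.na(distance) & distance >= large_threshold)
}

#' Classify every read pair of a sample over one gene
#'
#' Reads the alignments overlapping the gene, labels each end
#' ([label_ends()]), resolves mates by read name and SAM flags, computes the
#' inner mapping distance and applies the decision table. Every properly
#' resolvable pair is classified exactly once; reads without a mate in the
#' region are counted separately as `unpaired`.
#'
#' @param x BAM path or `GAlignments`.
#' @param model A [gene_model()].
#' @inheritParams classify_pair
#' @return Object of class `splice_classification`: list with `pairs` (one
#'   row per pair: `qname`, `label1`, `label2`, `feat_idx1`, `feat_idx2`,
#'   `jx1`, `jx2`, `distance`, `category`, `large`), `summary` (per-category
#'   `count`, `fraction` of classified pairs, `large_count`), `n_pairs`,
#'   `n_unpaired`, `gene_id`, and the thresholds used. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
classify_sample <- function(x, model,
                            expected_distance = 650,
                            large_threshold = 650) {
  ends <- label_ends(x, model)
  paired <- filter(ends, !is.na(.data$mate))
  unpaired_n <- ends |>
    filter(is.na(.data$mate)) |>
    nrow()

  # resolve mates: keep qnames seen exactly once as mate 1 and once as mate 2
  wide <- paired |>
    distinct(.data$qname, .data$mate, .keep_all = TRUE) |>
    group_by(.data$qname) |>
    filter(dplyr::n() == 2, sum(.data$mate == 1L) == 1L) |>
    ungroup()
  odd <- nrow(paired) - nrow(wide)
  unpaired_n <- unpaired_n + odd

  p1 <- filter(wide, .data$mate == 1L) |> arrange(.data$qname)
  p2 <- filter(wide, .data$mate == 2L) |> arrange(.data$qname)

  dist <- .pair_distance(p1$gstart, p1$gend, p2$gstart, p2$gend)
  same_feat <- p1$label %in% c("ex", "int") &
    p1$label == p2$label & p1$feat_idx == p2$feat_idx
  cls <- classify_pair(p1$label, p2$label, dist, same_feat,
                       expected_distance, large_threshold)

  pairs <- tibble(
    qname = p1$qname,
    label1 = p1$label, label2 = p2$label,
    feat_idx1 = p1$feat_idx, feat_idx2 = p2$feat_idx,
    jx1 = p1$jx, jx2 = p2$jx,
    distance = dist,
    category = cls$category, large = cls$large
  )

  structure(
    list(pairs = pairs,
         summary = .classification_summary(pairs),
         n_pairs = nrow(pairs),
         n_unpaired = unpaired_n,
         gene_id = model$gene_id,
         expected_distance = expected_distance,
         large_threshold = large_threshold),
    class = "splice_classification"
  )
}

.categories <- c("pre", "intermediate", "post", "unknown", "unclassified")

.classification_summary <- function(pairs) {
  tibble(category = factor(.categories, levels = .categories)) |>
    left_join(
      pairs |>
        group_by(category = factor(.data$category, levels = .categories)) |>
        summarise(count = dplyr::n(), large_count = sum(.data$large),
                  .groups = "drop"),
      by = "category"
    ) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           large_count = ifelse(is.na(.data$large_count), 0L,
                                .data$large_count),
           fraction = if (sum(.data$count) > 0) {
             .data$count / sum(.data$count)
           } else 0,
           category = as.character(.data$category))
}

#' @export
print.splice_classification <- function(x, ...) {
  cat(sprintf("<splice_classification> gene %s: %d pairs (%d unpaired ends)\n",
              x$gene_id, x$n_pairs, x$n_unpaired))
  print(x$summary)
  invisible(x)
}
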