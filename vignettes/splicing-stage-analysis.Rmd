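---
title: "Analysing splicing in progress: stages, order and recursive removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing splicing in progress: stages, order and recursive removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicestage)
```

## The problem and the model

Nuclear RNA, chromatin-associated RNA and capture-enriched pre-mRNA
libraries contain a mixture of transcripts at every stage of splicing:
fully unspliced precursors, intermediates with some introns removed, and
mature mRNA. A paired-end read sampled from such a mixture carries partial
information about the state of the molecule it came from: an end inside an
intron proves the intron was present; an end split exactly across an
annotated junction proves the intron was gone; an end crossing an
exon/intron border proves the boundary was intact. `splicestage` works
entirely from these observations, per gene, against one reference
transcript.

The package's assumptions are those of the underlying experiment:

* alignments are produced upstream by a splice-aware aligner that does not
  favour split alignments, with exactly one alignment per read; split ends
  are encoded with CIGAR `N` operations;
* one reference transcript describes the gene; exons and introns are
  numbered in transcription order (on the minus strand exon 1 has the
  highest genomic coordinate — indices flip, coordinates never do);
* steady-state read abundance over an intron is proportional to how long
  that intron remains in the transcript population, which is what makes
  median intron coverage informative about removal order;
* PCR duplicates are not removed; reproducibility across samples, not
  deduplication, guards against amplification artifacts.

## Stage classification

Each aligned end receives exactly one label — `int`, `ex`, `ex-ex`,
`ex-int`, or the bookkeeping labels `other` (split across a non-annotated
gap; the raw material of recursive-splicing detection) and `outside`. The
pair's category is a pure function of the two labels, the inner mapping
distance bucket, and (for `ex`/`ex` pairs) whether both ends share one
exon; `decision_table()` prints every cell. Two points are deliberate
choices rather than forced by the data model:

* **Expected-distance threshold, default 650 bp.** The expectation for the
  fragment-size distributions this method targets is "around 500 bp", but
  the operational cut used on real nuclear data is 650, and the *large*
  flag shares it. Both are configurable and logged.
* **Ambiguous cells.** Published descriptions of this classification leave
  a few label-pair cells visually ambiguous; this implementation resolves
  them from the category definitions (junction or multi-exon evidence ⇒
  post; any intronic contact ⇒ pre) and records the full table in the
  documentation so the resolution is inspectable.

Pairs with an `other`/`outside` end or undefined distance are
`unclassified` and reported as such — category counts always sum to the
number of pairs processed.

## Splice Site Index

`SSI = ex_ex / (ex_ex + ex_int)`, computed separately at each intron's 5′
and 3′ splice site from ends that span the site with at least `anchor`
bases on both sides (default 3 bp; a 1–2 bp overhang does not establish
spanning). The index is a ratio of read classes at one genomic point, so
it is scale-invariant and comparable between sites of very different
coverage. `NA` is reported where no informative reads exist rather than
imputing 0 or 1.

For retention ranking, a retained intron should have *both* SSIs low, so
the magnitude of intron *i* is the joint lowness
`(1 − SSI5 + 1 − SSI3) / 2` with an empirical rank p-value (fraction of
the other introns with magnitude at least as large). Descriptions of this
statistic are ambiguous between joint lowness and the 5′/3′ *difference*;
joint lowness matches the stated biology of retention, and the asymmetry
`|SSI5 − SSI3|` (informative about exon skipping) is reported as a
separate column so both readings remain available.

## Splicing order

Coverage evidence: `delta(i) = median_cov(intron_i+1) − median_cov(intron_i)`
for adjacent pairs only. Under 5′→3′ sequential removal deltas trend
positive; a strongly negative delta marks a downstream intron removed
early. The cutoff is the first quartile (linear-interpolation quantile,
`type = 7`) of the *negative* deltas, and candidacy is `delta <= Q1`. The
inclusive comparison is a deliberate numerical choice: in clean data a
single forced inversion produces exactly one negative delta, whose Q1 is
itself; a strict comparison would then flag nothing at all, while the
inclusive rule flags precisely the extreme difference the cutoff is
designed to find (with several negative deltas the two rules agree except
exactly at the quartile). Q3 is available via `quartile = "Q3"` for
sensitivity analysis. With fewer than four adjacent pairs the quartile is
unstable and a warning is raised.

Read evidence: `splice_ratio = seq / (seq + nonseq)` per adjacent pair —
close to 1 under sequential removal, close to 0 when the downstream intron
goes first, `NA` with no informative pairs (typical at whole-transcriptome
coverage, where the coverage route carries the signal alone).

`call_nonsequential()` requires: coverage candidacy in at least
`min_samples` RNA samples, **and** splice-ratio < 0.5 in every supporting
sample that has read evidence (waived at zero informative pairs), **and**
no candidacy in the DNA control. The AND-combination is a documented
choice for the case where the two evidence types disagree: coverage alone
may reflect mappability, read pairs alone may be mapping artifacts, so a
call must survive both where both exist. The control filter compares
candidate membership, not raw deltas: DNA deltas are noise around zero and
their magnitudes are not commensurable with RNA deltas. Pearson and
Spearman correlations between the two evidence types are reported
alongside the calls.

## Recursive splicing

Split gaps that exactly match an annotated intron are ordinary splicing
and are removed; everything else enters the inverted-coverage analysis.
The derivative convention is fixed as: a gap over `[s, e]` contributes a
+peak of its read count at `s` and a −peak at `e + 1` (derivative at *p*
compares *p* with *p* − 1). Positions that are simultaneously a split
start and a split end are excluded. Reported junction coordinates are
splice-site bases — donor `s − 1`, acceptor `e + 1` on the plus strand,
mirrored on the minus strand — so the junction matrix is in biological
coordinates, not gap coordinates.

Consensus across samples requires the same position with the same sign in
`min_samples` samples, each with per-sample magnitude ≥ 2 reads; the
reported value is the summed magnitude. The 2-read floor encodes the
empirical behaviour of DNA controls, where split positions are supported
by single reads and never recur across samples; matching is exact (0 bp
tolerance) — aligner soft-clip slippage should be fixed upstream, not
absorbed here.

Intra-intronic intervals bounded by a −peak and the next +peak whose
median coverage exceeds `k`× the host intron's median (default `k = 2`)
are flagged as putative novel exons and their bounding junctions removed
from the event list: flanking split reads plus elevated retained coverage
is the exonization signature, and only a nuclear-vs-cytoplasmic assay can
settle it, which is out of scope. The coverage-ratio rule replaces any
absolute "highest peak" cutoff — it is testable and scales with depth.

Motifs: the donor motif is the first two removed bases 3′ of the donor,
the acceptor motif the last two removed bases 5′ of the acceptor, read on
the coding strand (reverse-complemented on minus-strand genes); canonical
is GT/AG. Summary percentages cover only events with exactly one
non-annotated site, stratified by sample support; two-novel-site events
are excluded as likely novel exons. Gaps whose donor *and* acceptor are
both annotated (exon-skipping-like) are typed `skip_like` and excluded
from motif percentages.

## The simulator and what passing tests mean

`sim_config()`/`simulate_locus()`/`simulate_molecules()`/`simulate_reads()`
generate a single-gene locus and paired-end reads from configurable
mixtures of splicing intermediates, with a truth table per pair. Defaults,
chosen once to represent the targeted experiment type:

* 7 exons (6 introns) — large enough for order analysis with one forced
  inversion, small enough for second-scale tests; exons 80–200 bp, introns
  250–2000 bp;
* stage mixture 0.40 unspliced / 0.20 partially spliced / 0.40 mature —
  nuclear-RNA-like, substantial pre-mRNA alongside mature transcripts;
* partially spliced molecules have removed a *prefix* of the configured
  splicing order (snapshot semantics — the minimal model of intermediates
  consistent with orderly removal);
* fragments truncated-normal(300, 80), minimum 200 = 2 × the 100 bp read
  length — placing most pairs "within" the 650 bp expectation while the
  tail exercises the "outside" branch;
* canonical GT/AG planted at every annotated and recursive splice site;
  sequencing-error rate 0 by default (the pipeline starts downstream of
  alignment; an optional uniform substitution rate exists for robustness
  checks).

A DNA control is simulated as the fully unspliced mixture `c(1, 0, 0)`:
uniform gene-body coverage, no junction or split reads — the two
properties the control contributes to the analysis. The simulator does
**not** model capture-probe bias, indels, soft-clips, alignment error or
multi-isoform loci. Passing tests therefore demonstrate correctness of
the *method logic* under its stated read model, not robustness to aligner
pathologies; on real data the published guidance applies — use several
samples and a DNA control.

Test and verification problem sizes are chosen as the smallest that make
the statistical properties sharp: 10,000 pairs for oracle-equivalence of
classification, 50,000 pairs × 3 seeds for order recovery, 4 samples for
recursive consensus, 12,000 pairs × 2 samples for novel-exon flagging.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout, matching GTF, SAM and the
  R/Bioconductor range containers end to end.
* Median coverage uses the standard even-length interpolating median;
  depth counts aligned blocks only (`N` gaps contribute nothing).
* SSI and splice-ratio report `NA` on zero denominators; retention
  ranking requires ≥ 3 introns with both SSIs defined and errors
  otherwise; ties in retention magnitude break by ascending intron index.
* Single-exon genes are rejected at model construction (no introns to
  analyse); a gene with zero overlapping reads yields zero-count
  summaries and a warning, not an error.
* Re-running the pipeline on identical inputs is byte-identical; the only
  randomness in the package lives in the simulator, behind explicit
  seeds.

## Known limitations

One reference transcript per gene (no multi-isoform deconvolution); local
order only — the global removal order of a transcript is not identifiable
from snapshots; no lariat/branch-point detection; no splice-site strength
scoring; novel-exon vs recursive-intermediate disambiguation requires
experimental follow-up.
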