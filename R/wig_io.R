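#' Write signed gap peaks as a wiggle track
#'
#' variableStep, span=1; the value at each position is the signed peak
#' magnitude (+ for split starts, - for split ends). One track per sample.
#'
#' @param peaks A [gap_peaks()] or consensus tibble with `pos`, `sign`,
#'   `magnitude`.
#' @param path Output path.
#' @param chrom Chromosome name for the track.
#' @param name Track name.
#' @return `path`, invisibly.
#' @export
write_peaks_wig <- function(peaks, path, chrom, name = "gap_peaks") {
  lines <- c(
    sprintf("track type=wiggle_0 name=\"%s\"", name),
    sprintf("variableStep chrom=%s span=1", chrom),
    sprintf("%d %d", peaks$pos, peaks$sign * peaks$magnitude)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed-peak wiggle track
#'
#' Inverse of [write_peaks_wig()]: peaks written and re-read are identical
#' in position, sign and magnitude.
#'
#' @param path Wiggle path (single variableStep track).
#' @return Tibble `pos`, `sign`, `magnitude` with attribute `chrom`.
#' @export
read_peaks_wig <- function(path) {
  lines <- readLines(path)
  decl <- grep("^variableStep", lines, value = TRUE)
  chrom <- str_match(decl[1], "chrom=(\\S+)")[, 2]
  dat <- lines[grepl("^-?[0-9]+ -?[0-9]+$", lines)]
  if (length(dat) == 0) {
    out <- tibble(pos = integer(), sign = integer(), magnitude = integer())
  } else {
    m <- do.call(rbind, strsplit(dat, " ", fixed = TRUE))
    val <- as.integer(m[, 2])
    out <- tibble(pos = as.integer(m[, 1]),
                  sign = ifelse(val >= 0, 1L, -1L),
                  magnitude = abs(val))
  }
  attr(out, "chrom") <- chrom
  out
}
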