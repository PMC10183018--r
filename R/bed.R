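#' Write intervals as 3-column BED
#'
#' Intervals must be sorted and non-overlapping; coordinates are
#' written 0-based half-open (the BED convention) via rtracklayer, so a
#' write-then-read round trip reproduces the input exactly.
#'
#' @param intervals A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
  if (length(intervals)) {
    ord <- order(match(as.character(seqnames(intervals)),
                       seqlevels(intervals)), start(intervals))
    if (!identical(ord, seq_along(intervals)))
      stop("intervals must be sorted")
    if (!IRanges::isDisjoint(intervals))
      stop("intervals must be non-overlapping")
  }
  df <- data.frame(chrom = as.character(seqnames(intervals)),
                   start = start(intervals) - 1L,
                   end = end(intervals))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' @param path Path to a BED3+ file.
#' @param layout Optional [GenomeLayout-class] supplying seqinfo.
#' @return A sorted [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path, layout = NULL) {
  if (file.size(path) == 0)
    gr <- GRanges()
  else
    gr <- granges(import(path, format = "bed"))
  if (!is.null(layout)) {
    seqlevels(gr) <- seqlevels(seqinfo(layout))
    seqinfo(gr) <- seqinfo(layout)
  }
  sort(gr)
}
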