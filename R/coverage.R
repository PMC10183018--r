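#' Read a bedGraph coverage track
#'
#' Builds a full-genome depth vector per chromosome; positions not
#' listed in the file have depth 0. Overlapping intervals or negative
#' depths are format errors.
#'
#' @param path Path to a bedGraph file (0-based half-open on disk;
#'   converted by rtracklayer).
#' @param layout The [GenomeLayout-class] the track belongs to.
#' @param sampleId Sample identifier attached to the track.
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(path, layout, sampleId = basename(path)) {
  gr <- import(path, format = "bedGraph")
  CoverageTrack(gr, layout, sampleId)
}

#' Construct a CoverageTrack from scored intervals
#'
#' @param intervals A [GenomicRanges::GRanges] with a numeric `score`
#'   column (read depth). Must be non-overlapping per chromosome.
#' @param layout A [GenomeLayout-class].
#' @param sampleId Sample identifier.
#' @return A [CoverageTrack-class].
#' @export
CoverageTrack <- function(intervals, layout, sampleId = "sample") {
  sl <- chromLengths(layout)
  if (length(intervals)) {
    extra <- setdiff(unique(as.character(seqnames(intervals))), names(sl))
    if (length(extra))
      stop("format error: chromosome(s) not in layout: ",
           paste(extra, collapse = ", "))
    if (!IRanges::isDisjoint(intervals))
      stop("format error: overlapping coverage intervals")
    if (any(intervals$score < 0))
      stop("format error: negative coverage value")
    if (any(end(intervals) > sl[as.character(seqnames(intervals))]))
      stop("format error: coverage interval beyond chromosome end")
    seqlevels(intervals) <- names(sl)
  } else {
    intervals <- GRanges(seqinfo = seqinfo(layout))
    intervals$score <- numeric(0)
  }
  cov <- coverage(intervals, weight = "score", width = sl)[names(sl)]
  new("CoverageTrack", sampleId = sampleId,
      coverage = cov, seqinfo = seqinfo(layout))
}

#' @rdname CoverageTrack-class
#' @export
setMethod("sampleId", "CoverageTrack", function(x) x@sampleId)

#' Per-chromosome depth vectors
#'
#' @param x A [CoverageTrack-class].
#' @return An [IRanges::RleList] of depths, one per chromosome.
#' @export
coverageRle <- function(x) {
  stopifnot(is(x, "CoverageTrack"))
  x@coverage
}

setMethod("show", "CoverageTrack", function(object) {
  m <- sum(vapply(object@coverage, function(r)
    sum(as.numeric(runValue(r)) * runLength(r)), 0)) /
    sum(as.numeric(seqlengths(object@seqinfo)))
  cat("CoverageTrack for sample", object@sampleId, "over",
      length(object@coverage), "chromosome(s); mean depth",
      sprintf("%.1f", m), "\n")
})

#' Write a CoverageTrack as bedGraph
#'
#' Zero-depth runs are omitted, matching the reader's convention that
#' unlisted positions have depth 0.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  gr <- methods::as(track@coverage, "GRanges")
  gr <- gr[gr$score > 0]
  seqinfo(gr) <- track@seqinfo
  export(gr, path, format = "bedGraph")
  invisible(path)
}
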