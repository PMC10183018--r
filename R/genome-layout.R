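#' Construct a GenomeLayout
#'
#' @param chromLengths Named integer vector of chromosome lengths in
#'   base pairs, in assembly order.
#' @param gaps A [GenomicRanges::GRanges] of assembly-gap intervals
#'   (runs of N in the reference). Sorted and reduced on construction.
#'
#' @return A [GenomeLayout-class] object.
#' @examples
#' layout <- GenomeLayout(c(chr1 = 10000L, chr2 = 5000L),
#'                        GRanges("chr1", IRanges(2001, 2500)))
#' chromLengths(layout)
#' @export
GenomeLayout <- function(chromLengths, gaps = GRanges()) {
  if (is.null(names(chromLengths)))
    stop("chromLengths must be a named vector")
  si <- Seqinfo(seqnames = names(chromLengths),
                seqlengths = as.integer(chromLengths))
  if (length(gaps)) {
    seqlevels(gaps) <- seqlevels(si)
    seqinfo(gaps) <- si
    gaps <- reduce(sort(granges(gaps)))
  } else {
    gaps <- GRanges(seqinfo = si)
  }
  new("GenomeLayout", seqinfo = si, gaps = gaps)
}

#' @rdname GenomeLayout-class
#' @export
setMethod("seqinfo", "GenomeLayout", function(x) x@seqinfo)

#' @rdname GenomeLayout-class
#' @export
setMethod("assemblyGaps", "GenomeLayout", function(x) x@gaps)

#' Chromosome lengths of a layout
#'
#' @param x A [GenomeLayout-class].
#' @return Named integer vector of lengths in base pairs.
#' @export
chromLengths <- function(x) {
  stopifnot(is(x, "GenomeLayout"))
  seqlengths(x@seqinfo)
}

#' Total assembly length
#'
#' @param x A [GenomeLayout-class].
#' @param excludeGaps If `TRUE`, subtract total assembly-gap bases.
#' @return Length in base pairs.
#' @export
genomeLength <- function(x, excludeGaps = FALSE) {
  stopifnot(is(x, "GenomeLayout"))
  tot <- sum(as.numeric(chromLengths(x)))
  if (excludeGaps) tot <- tot - sum(as.numeric(width(x@gaps)))
  tot
}

setMethod("show", "GenomeLayout", function(object) {
  sl <- chromLengths(object)
  cat("GenomeLayout with", length(sl), "chromosome(s),",
      format(sum(as.numeric(sl)), big.mark = ","), "bp;",
      length(object@gaps), "assembly gap(s) (",
      format(sum(width(object@gaps)), big.mark = ","), "bp )\n")
})

## gap mask as a logical RleList over the full layout
gapMask <- function(layout) {
  sl <- chromLengths(layout)
  cov <- coverage(assemblyGaps(layout), width = sl)
  methods::as(cov > 0, "RleList")[names(sl)]
}
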