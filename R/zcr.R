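#' Detect zero-coverage regions (ZCRs)
#'
#' A ZCR is a maximal run of reference positions with zero read depth
#' over non-gap sequence, at least `minLength` bases long (2 kb by
#' default, boundary inclusive). Assembly gaps are masked first; by
#' default a gap terminates a run, so a ZCR is never called across a
#' gap. With `bridgeGaps = TRUE` gap bases do not terminate runs: a
#' zero run interrupted by gaps is retained when its *non-gap* length
#' reaches `minLength`, and its non-gap sub-intervals are reported.
#'
#' @param track A [CoverageTrack-class].
#' @param layout A [GenomeLayout-class]; must contain every chromosome
#'   of the track.
#' @param minLength Minimum run length in bases (default 2000).
#' @param bridgeGaps Whether assembly gaps bridge zero runs.
#' @return A [ZCRSet-class].
#' @examples
#' layout <- GenomeLayout(c(chr = 10000L))
#' cov <- GRanges("chr", IRanges(c(1, 3501), c(1000, 10000)), score = 8)
#' track <- CoverageTrack(cov, layout, "s1")   # zero depth on 1001-3500
#' detectZcrs(track, layout)
#' @export
detectZcrs <- function(track, layout, minLength = 2000L,
                       bridgeGaps = FALSE) {
  stopifnot(is(track, "CoverageTrack"), is(layout, "GenomeLayout"))
  if (minLength <= 0L) stop("minLength must be positive")
  sl <- chromLengths(layout)
  miss <- setdiff(names(coverageRle(track)), names(sl))
  if (length(miss))
    stop("track chromosome(s) absent from layout: ",
         paste(miss, collapse = ", "))
  gaps <- gapMask(layout)
  out <- list()
  for (chr in names(sl)) {
    zero <- coverageRle(track)[[chr]] == 0L
    gap <- gaps[[chr]]
    if (bridgeGaps) {
      ## candidate runs of (zero | gap); qualify on non-gap length,
      ## then report the non-gap pieces of each qualifying run
      cand <- methods::as(zero | gap, "IRanges")
      gapr <- methods::as(gap, "IRanges")
      gw <- integer(length(cand))
      if (length(cand) && length(gapr)) {
        ov <- findOverlaps(cand, gapr)
        if (length(ov)) {
          piw <- width(pintersect(cand[queryHits(ov)],
                                  gapr[subjectHits(ov)]))
          agg <- rowsum(piw, queryHits(ov))
          gw[as.integer(rownames(agg))] <- agg[, 1]
        }
      }
      ngw <- width(cand) - gw
      runs <- setdiff(cand[ngw >= minLength & ngw > 0L], gapr)
    } else {
      runs <- methods::as(zero & !gap, "IRanges")
      runs <- runs[width(runs) >= minLength]
    }
    if (length(runs))
      out[[chr]] <- GRanges(factor(chr, levels = names(sl)), runs)
  }
  gr <- if (length(out)) sort(do.call(c, unname(out)))
        else GRanges(factor(levels = names(sl)), IRanges())
  seqlevels(gr) <- names(sl)
  seqinfo(gr) <- seqinfo(layout)
  new("ZCRSet", sampleId = sampleId(track), intervals = gr,
      minLength = as.integer(minLength))
}

#' @rdname ZCRSet-class
#' @export
setMethod("sampleId", "ZCRSet", function(x) x@sampleId)

#' @rdname ZCRSet-class
#' @export
setMethod("zcrRanges", "ZCRSet", function(x) x@intervals)

#' @rdname ZCRSet-class
#' @export
setMethod("minLength", "ZCRSet", function(x) x@minLength)

setMethod("show", "ZCRSet", function(object) {
  cat("ZCRSet for sample", object@sampleId, ":",
      length(object@intervals), "region(s) >=", object@minLength, "bp,",
      format(sum(width(object@intervals)), big.mark = ","),
      "bp total\n")
})

#' Fraction of the genome covered by ZCRs
#'
#' @param zcrs A [ZCRSet-class].
#' @param layout A [GenomeLayout-class].
#' @param denominator `"full"` (total assembly length, default) or
#'   `"nongap"` (assembly length minus gap bases).
#' @return Percentage of base pairs covered by ZCRs.
#' @export
genomeZcrFraction <- function(zcrs, layout,
                              denominator = c("full", "nongap")) {
  stopifnot(is(zcrs, "ZCRSet"), is(layout, "GenomeLayout"))
  denominator <- match.arg(denominator)
  denom <- genomeLength(layout, excludeGaps = denominator == "nongap")
  if (denom <= 0) stop("empty layout")
  100 * sum(as.numeric(width(zcrRanges(zcrs)))) / denom
}
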