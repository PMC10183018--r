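#' Per-locus absence matrix across samples
#'
#' For each locus and sample, the fraction of locus bases covered by
#' that sample's ZCRs; a locus is called absent in a sample when the
#' fraction reaches `threshold` (boundary inclusive, default 0.5).
#'
#' @param zcrList Named list of [ZCRSet-class] objects, one per sample
#'   (at least two).
#' @param loci Named [GenomicRanges::GRanges] of loci (e.g. gene spans
#'   of a cluster of interest, or fixed windows).
#' @param threshold Absence-call threshold on the covered fraction.
#' @return A [PresenceAbsenceMatrix-class].
#' @export
locusAbsenceMatrix <- function(zcrList, loci, threshold = 0.5) {
  if (length(zcrList) < 2L)
    stop("at least two samples required")
  if (is.null(names(zcrList)) || any(names(zcrList) == ""))
    stop("zcrList must be named by sample")
  if (is.null(names(loci)) || any(names(loci) == ""))
    stop("loci must be named")
  if (any(width(loci) <= 0L))
    stop("zero-length locus")
  frac <- matrix(0, length(loci), length(zcrList),
                 dimnames = list(names(loci), names(zcrList)))
  for (s in names(zcrList)) {
    z <- zcrRanges(zcrList[[s]])
    if (!length(z)) next
    ov <- findOverlaps(loci, z, ignore.strand = TRUE)
    if (!length(ov)) next
    inter <- width(pintersect(loci[queryHits(ov)], z[subjectHits(ov)],
                              ignore.strand = TRUE))
    agg <- rowsum(inter, queryHits(ov))
    frac[as.integer(rownames(agg)), s] <-
      agg[, 1] / width(loci)[as.integer(rownames(agg))]
  }
  new("PresenceAbsenceMatrix", loci = loci, fraction = frac,
      absent = frac >= threshold, threshold = threshold)
}

#' @rdname PresenceAbsenceMatrix-class
#' @export
setMethod("absenceFraction", "PresenceAbsenceMatrix",
          function(x) x@fraction)

#' @rdname PresenceAbsenceMatrix-class
#' @export
setMethod("absenceCalls", "PresenceAbsenceMatrix",
          function(x) x@absent)

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat("PresenceAbsenceMatrix:", nrow(object@fraction), "locus/loci x",
      ncol(object@fraction), "sample(s); threshold",
      object@threshold, "\n")
})

#' Loci with discordant presence/absence calls
#'
#' @param x A [PresenceAbsenceMatrix-class].
#' @return Character vector of locus names where not all samples share
#'   the same binary call — the signature of an alternative haplotype
#'   segregating among the samples.
#' @export
discordantLoci <- function(x) {
  stopifnot(is(x, "PresenceAbsenceMatrix"))
  a <- absenceCalls(x)
  rownames(a)[rowSums(a) > 0L & rowSums(a) < ncol(a)]
}

#' Complementary presence/absence locus pairs
#'
#' Reports unordered pairs of loci whose binary absence vectors across
#' samples are exact complements, neither vector being constant — the
#' pattern of two alternative haplotypes assembled in tandem in the
#' reference, where each individual carries one locus and lacks the
#' other.
#'
#' @param x A [PresenceAbsenceMatrix-class] with at least two loci.
#' @return `data.frame` with columns `locus_a`, `locus_b` (one row per
#'   unordered pair; zero rows when none).
#' @export
complementaryPairs <- function(x) {
  stopifnot(is(x, "PresenceAbsenceMatrix"))
  a <- absenceCalls(x)
  empty <- data.frame(locus_a = character(0), locus_b = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(a) < 2L) return(empty)
  variable <- rowSums(a) > 0L & rowSums(a) < ncol(a)
  idx <- which(variable)
  rows <- list()
  if (length(idx) >= 2L) {
    for (i in seq_len(length(idx) - 1L)) {
      for (j in seq(i + 1L, length(idx))) {
        if (all(a[idx[i], ] == !a[idx[j], ]))
          rows[[length(rows) + 1L]] <- data.frame(
            locus_a = rownames(a)[idx[i]],
            locus_b = rownames(a)[idx[j]],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
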