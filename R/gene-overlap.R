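#' Flag genes whose exons overlap ZCRs
#'
#' A gene is flagged when at least one base of at least one exon of its
#' canonical transcript intersects at least one ZCR interval.
#' Intron-only overlap does not flag a gene. With
#' `useExons = "gene_span"` the whole gene span is intersected instead
#' (an all-transcript union can be supplied as a catalog built that
#' way).
#'
#' @param zcrs A [ZCRSet-class].
#' @param catalog A [GeneCatalog-class] sharing the chromosome
#'   namespace.
#' @param useExons `"canonical"` (default) intersects canonical
#'   exons; `"gene_span"` intersects full gene spans.
#' @return Named logical vector over all genes of the catalog.
#' @export
flagGenesByZcr <- function(zcrs, catalog,
                           useExons = c("canonical", "gene_span")) {
  stopifnot(is(zcrs, "ZCRSet"), is(catalog, "GeneCatalog"))
  useExons <- match.arg(useExons)
  z <- zcrRanges(zcrs)
  flags <- setNames(rep(FALSE, length(geneIds(catalog))),
                    geneIds(catalog))
  if (!length(z)) return(flags)
  if (useExons == "canonical") {
    exl <- exonRanges(catalog)
    ex <- unlist(exl, use.names = FALSE)
    ex_gene <- rep(names(exl), lengths(exl))
    hit <- unique(ex_gene[!is.na(findOverlaps(ex, z, select = "first",
                                              ignore.strand = TRUE))])
  } else {
    g <- geneRanges(catalog)
    hit <- names(g)[!is.na(findOverlaps(g, z, select = "first",
                                        ignore.strand = TRUE))]
  }
  flags[hit] <- TRUE
  flags
}

#' Combine per-sample gene flags
#'
#' @param flagList Named list of per-sample flag vectors from
#'   [flagGenesByZcr()], all over the same gene universe.
#' @return A [GeneFlagTable-class]; the combined column is the
#'   element-wise OR across samples.
#' @export
combineFlags <- function(flagList) {
  if (!length(flagList)) stop("at least one sample required")
  if (is.null(names(flagList)) || any(names(flagList) == ""))
    stop("flagList must be named by sample")
  universe <- names(flagList[[1]])
  same <- vapply(flagList, function(f)
    identical(sort(names(f)), sort(universe)), NA)
  if (!all(same))
    stop("inconsistent gene universes across samples")
  m <- vapply(flagList, function(f) f[universe],
              logical(length(universe)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(universe),
                                   dimnames = list(universe,
                                                   names(flagList)))
  new("GeneFlagTable", flags = m)
}

#' @rdname GeneFlagTable-class
#' @export
setMethod("sampleFlags", "GeneFlagTable", function(x) x@flags)

#' @rdname GeneFlagTable-class
#' @export
setMethod("combinedFlags", "GeneFlagTable", function(x)
  rowSums(x@flags) > 0L)

setMethod("show", "GeneFlagTable", function(object) {
  cat("GeneFlagTable:", nrow(object@flags), "gene(s) x",
      ncol(object@flags), "sample(s);",
      sum(combinedFlags(object)), "flagged in >=1 sample\n")
})

#' Gene-set ZCR overlap summary
#'
#' For each gene set and each sample column plus the combined column,
#' the count and percentage of set members flagged as ZCR-overlapped.
#'
#' @param flags A [GeneFlagTable-class].
#' @param catalogSets Named list of character vectors (gene sets); every
#'   member must exist in the flag table's gene universe.
#' @return `data.frame` with columns `set`, `column` (sample name or
#'   `"Comb."`), `n_flagged`, `n_total`, `percent` (one decimal).
#' @export
genesetZcrSummary <- function(flags, catalogSets) {
  stopifnot(is(flags, "GeneFlagTable"))
  universe <- rownames(sampleFlags(flags))
  cols <- cbind(sampleFlags(flags), Comb. = combinedFlags(flags))
  rows <- list()
  for (set_name in names(catalogSets)) {
    members <- catalogSets[[set_name]]
    if (!length(members))
      stop("empty gene set: ", set_name)
    missing <- setdiff(members, universe)
    if (length(missing))
      stop("gene(s) in set '", set_name, "' missing from universe: ",
           paste(head(missing, 5), collapse = ", "))
    for (cn in colnames(cols)) {
      k <- sum(cols[members, cn])
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, column = cn, n_flagged = k,
        n_total = length(members),
        percent = round(100 * k / length(members), 1))
    }
  }
  do.call(rbind, rows)
}

#' Read a two-column gene-set catalog TSV
#'
#' @param path TSV with columns `gene_id`, `set_name` (no header).
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene_id", "set_name"),
                   stringsAsFactors = FALSE)
  split(df$gene_id, df$set_name)
}
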