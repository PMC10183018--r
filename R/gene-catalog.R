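#' Construct a GeneCatalog
#'
#' @param genes Named [GenomicRanges::GRanges] of gene spans with
#'   metadata columns `gene_id` and `transcript_id` (the canonical
#'   transcript).
#' @param exons,cds Named [GenomicRanges::GRangesList] of exon / CDS
#'   segments per gene, in the same order as `genes`.
#'
#' @return A [GeneCatalog-class].
#' @export
GeneCatalog <- function(genes, exons, cds) {
  if (is.null(names(genes)) && !is.null(genes$gene_id))
    names(genes) <- genes$gene_id
  strip <- function(g) {
    g <- sort(granges(g))
    names(g) <- NULL
    g
  }
  exons <- GRangesList(lapply(exons, strip))
  cds <- GRangesList(lapply(cds, strip))
  new("GeneCatalog", genes = genes, exons = exons[names(genes)],
      cds = cds[names(genes)])
}

#' @rdname GeneCatalog-class
#' @export
setMethod("geneRanges", "GeneCatalog", function(x) x@genes)

#' @rdname GeneCatalog-class
#' @export
setMethod("exonRanges", "GeneCatalog", function(x) x@exons)

#' @rdname GeneCatalog-class
#' @export
setMethod("cdsRanges", "GeneCatalog", function(x) x@cds)

#' @rdname GeneCatalog-class
#' @export
setMethod("geneIds", "GeneCatalog", function(x) names(x@genes))

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog with", length(object@genes), "gene(s) on",
      length(unique(as.character(seqnames(object@genes)))),
      "chromosome(s)\n")
})

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features and selects one canonical
#' transcript per gene: a transcript tagged `canonical` or
#' `Ensembl_canonical` if present, otherwise the transcript with the
#' longest total CDS, ties broken by lexicographically smallest
#' transcript identifier.
#'
#' @param path Path to a GFF3 file.
#' @return A [GeneCatalog-class].
#' @export
readGff3Genes <- function(path) {
  gr <- import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  parts <- gr[type %in% c("exon", "CDS")]

  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("parse error: gene with unknown strand symbol")

  mrna_parent <- vapply(mrnas$Parent, function(p) p[1], "")
  part_parent <- vapply(parts$Parent, function(p) p[1], "")
  canonical <- rep(FALSE, length(mrnas))
  if (!is.null(mrnas$tag))
    canonical <- vapply(mrnas$tag, function(tg)
      any(grepl("canonical", tg, ignore.case = TRUE)), NA)

  cds_len <- vapply(mrnas$ID, function(tx)
    sum(width(parts[part_parent == tx &
                    as.character(parts$type) == "CDS"])), 0L)

  pick <- function(gid) {
    i <- which(mrna_parent == gid)
    if (!length(i))
      stop("malformed annotation: gene ", gid, " has no mRNA")
    j <- i[canonical[i]]
    if (!length(j)) {
      mx <- i[cds_len[i] == max(cds_len[i])]
      j <- mx[order(mrnas$ID[mx])][1]
    } else j <- j[order(mrnas$ID[j])][1]
    mrnas$ID[j]
  }

  ids <- genes$ID
  tx <- vapply(ids, pick, "")
  exl <- list(); cdl <- list()
  for (k in seq_along(ids)) {
    sel <- parts[part_parent == tx[k]]
    ex <- sort(granges(sel[as.character(sel$type) == "exon"]))
    cd <- sort(granges(sel[as.character(sel$type) == "CDS"]))
    if (sum(width(cd)) %% 3L != 0L)
      stop("malformed annotation: CDS length of gene ", ids[k],
           " (transcript ", tx[k], ") is not divisible by 3")
    exl[[ids[k]]] <- ex
    cdl[[ids[k]]] <- cd
  }
  g <- granges(genes)
  names(g) <- ids
  g$gene_id <- ids
  g$transcript_id <- unname(tx)
  GeneCatalog(g, GRangesList(exl), GRangesList(cdl))
}

#' Write a GeneCatalog as GFF3
#'
#' Emits gene/mRNA/exon/CDS features for the canonical transcript of
#' each gene; [readGff3Genes()] on the result reproduces the catalog.
#'
#' @param catalog A [GeneCatalog-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGff3Genes <- function(catalog, path) {
  g <- geneRanges(catalog)
  rows <- list()
  for (i in seq_along(g)) {
    gid <- names(g)[i]; tid <- g$transcript_id[i]
    gg <- granges(g[i]); gg$type <- "gene"; gg$ID <- gid
    gg$Parent <- IRanges::CharacterList(character(0))
    mm <- granges(g[i]); mm$type <- "mRNA"; mm$ID <- tid
    mm$Parent <- IRanges::CharacterList(gid)
    ex <- exonRanges(catalog)[[gid]]
    cd <- cdsRanges(catalog)[[gid]]
    strand(ex) <- strand(gg); strand(cd) <- strand(gg)
    if (length(ex)) {
      ex$type <- "exon"; ex$ID <- NA_character_
      ex$Parent <- IRanges::CharacterList(as.list(rep(tid, length(ex))))
    }
    if (length(cd)) {
      cd$type <- "CDS"; cd$ID <- NA_character_
      cd$Parent <- IRanges::CharacterList(as.list(rep(tid, length(cd))))
      ## phase: bases to skip at piece start, in translation order
      w <- width(cd)
      before <- if (as.character(strand(gg)) == "+")
        c(0L, cumsum(w))[seq_along(w)]
      else rev(c(0L, cumsum(rev(w)))[seq_along(w)])
      cd$phase <- (3L - before %% 3L) %% 3L
    }
    rows[[i]] <- c(gg, mm, ex, cd)
  }
  out <- do.call(c, rows)
  export(out, path, format = "gff3")
  invisible(path)
}
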