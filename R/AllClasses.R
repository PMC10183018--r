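## Central S4 containers. All genomic intervals are GRanges (1-based,
## closed), the native convention of the GenomicRanges stack; 0-based
## half-open formats (BED, bedGraph) are converted at the I/O boundary
## by rtracklayer.

#' GenomeLayout: chromosome lengths plus assembly gaps
#'
#' Describes the reference assembly the pipeline operates on: an ordered
#' set of chromosomes with lengths, and the assembly-gap intervals (runs
#' of N) that must be masked before zero-coverage analysis because no
#' read can map within them.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with chromosome names and
#'   lengths.
#' @slot gaps A [GenomicRanges::GRanges] of assembly gaps, sorted and
#'   disjoint, within chromosome bounds.
#'
#' @seealso [GenomeLayout()], [assemblyGaps()], [chromLengths()]
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(seqinfo = "Seqinfo", gaps = "GRanges"))

setValidity("GenomeLayout", function(object) {
  sl <- seqlengths(object@seqinfo)
  if (length(sl) == 0L)
    return("layout must contain at least one chromosome")
  if (anyNA(sl) || any(sl <= 0))
    return("all chromosome lengths must be positive and known")
  g <- object@gaps
  if (length(g)) {
    if (!all(as.character(seqnames(g)) %in% names(sl)))
      return("gap intervals on chromosomes absent from the layout")
    if (any(start(g) < 1L) ||
        any(end(g) > sl[as.character(seqnames(g))]))
      return("gap intervals extend beyond chromosome bounds")
    if (!IRanges::isDisjoint(g))
      return("gap intervals must be non-overlapping")
  }
  TRUE
})

#' GeneCatalog: gene models with canonical-transcript structure
#'
#' One canonical transcript per gene: the gene span, its exons and its
#' CDS segments. Variant consequences and exon/ZCR overlap are always
#' evaluated on this transcript.
#'
#' @slot genes A [GenomicRanges::GRanges], one range per gene (the gene
#'   span), named by `gene_id`, with metadata columns `gene_id` and
#'   `transcript_id`.
#' @slot exons A [GenomicRanges::GRangesList] of exons per gene, named
#'   by `gene_id`, sorted, non-overlapping within a gene.
#' @slot cds A [GenomicRanges::GRangesList] of CDS segments per gene;
#'   total CDS width is divisible by 3.
#'
#' @seealso [GeneCatalog()], [readGff3Genes()]
#' @exportClass GeneCatalog
setClass("GeneCatalog",
  representation(genes = "GRanges", exons = "GRangesList",
                 cds = "GRangesList"))

setValidity("GeneCatalog", function(object) {
  ids <- names(object@genes)
  if (is.null(ids) || anyDuplicated(ids))
    return("genes must be uniquely named by gene_id")
  if (!identical(ids, names(object@exons)) ||
      !identical(ids, names(object@cds)))
    return("exons and cds must be named identically to genes")
  if (!all(strand(object@genes) %in% c("+", "-")))
    return("gene strand must be '+' or '-'")
  w <- sum(width(object@cds))
  bad <- ids[w %% 3L != 0L]
  if (length(bad))
    return(paste0("CDS length not divisible by 3 for gene(s): ",
                  paste(head(bad, 5), collapse = ", ")))
  if (any(!IRanges::isDisjoint(object@exons)))
    return("exons within a gene must be non-overlapping")
  TRUE
})

#' CoverageTrack: per-chromosome read depth
#'
#' Read depth across an assembly for one sample, held as a run-length
#' encoded vector per chromosome. Positions absent from the source
#' bedGraph have depth 0.
#'
#' @slot sampleId Sample identifier.
#' @slot coverage An [IRanges::RleList], one non-negative Rle per
#'   chromosome, each of full chromosome length.
#' @slot seqinfo The [GenomeInfoDb::Seqinfo] of the layout the track was
#'   built against.
#'
#' @seealso [readBedGraph()], [detectZcrs()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(sampleId = "character", coverage = "RleList",
                 seqinfo = "Seqinfo"))

setValidity("CoverageTrack", function(object) {
  sl <- seqlengths(object@seqinfo)
  if (!identical(sort(names(object@coverage)), sort(names(sl))))
    return("coverage chromosomes must match the layout")
  len <- vapply(object@coverage, length, 0L)
  if (!all(len == sl[names(object@coverage)]))
    return("each coverage Rle must span its full chromosome length")
  if (any(vapply(object@coverage, function(x) any(runValue(x) < 0), NA)))
    return("coverage depth must be non-negative")
  TRUE
})

#' ZCRSet: zero-coverage regions for one sample
#'
#' Maximal runs of zero read depth over non-gap reference sequence, at
#' least `minLength` bases long (2 kb by default). A ZCR is a proxy for
#' a homozygous deletion or a region too divergent for reads to map.
#'
#' @slot sampleId Sample identifier.
#' @slot intervals Sorted, disjoint [GenomicRanges::GRanges], each of
#'   width >= `minLength`, disjoint from assembly gaps.
#' @slot minLength Minimum reported run length in bases.
#'
#' @seealso [detectZcrs()], [genomeZcrFraction()]
#' @exportClass ZCRSet
setClass("ZCRSet",
  representation(sampleId = "character", intervals = "GRanges",
                 minLength = "integer"))

setValidity("ZCRSet", function(object) {
  if (object@minLength <= 0L)
    return("minLength must be positive")
  ## per-interval width >= minLength holds in the default (non-
  ## bridging) mode and is enforced by detectZcrs; under gap bridging
  ## a qualifying run's non-gap pieces may individually be shorter
  if (length(object@intervals) &&
      !IRanges::isDisjoint(object@intervals))
    return("intervals must be non-overlapping")
  TRUE
})

#' VariantTable: decomposed biallelic variant records with genotypes
#'
#' One row per distinct (chrom, pos, ref, alt); multi-allelic VCF sites
#' are decomposed on read. Genotypes are stored as the number of copies
#' of the row's alternate allele each sample carries (0, 1, 2, or NA
#' for missing).
#'
#' @slot records `data.frame` with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `type` (one of `"SNV"`, `"insertion"`, `"deletion"`,
#'   `"other"`).
#' @slot info `data.frame` of numeric site annotations (e.g. `QD`,
#'   `FS`), row-aligned with `records`.
#' @slot genotypes Integer matrix, rows aligned with `records`, one
#'   column per sample.
#'
#' @seealso [readVariants()], [hardFilter()], [zygosityPartition()]
#' @exportClass VariantTable
setClass("VariantTable",
  representation(records = "data.frame", info = "data.frame",
                 genotypes = "matrix"))

setValidity("VariantTable", function(object) {
  r <- object@records
  need <- c("chrom", "pos", "ref", "alt", "type")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:",
                 paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (any(!grepl("^[ACGT]+$", r$ref)) || any(!grepl("^[ACGT]+$", r$alt)))
      return("ref and alt must be non-empty strings over {A,C,G,T}")
    key <- paste(r$chrom, r$pos, r$ref, r$alt)
    if (anyDuplicated(key))
      return("duplicate (chrom,pos,ref,alt) records")
  }
  if (nrow(object@info) != nrow(r) || nrow(object@genotypes) != nrow(r))
    return("info and genotypes must be row-aligned with records")
  gt <- object@genotypes
  if (length(gt) && !all(gt[!is.na(gt)] %in% 0:2))
    return("genotype allele copies must be 0, 1, 2 or NA")
  TRUE
})

#' GeneFlagTable: per-sample and combined ZCR-overlap flags
#'
#' For each gene, whether at least one exon base intersects a ZCR, per
#' sample; the combined column is the element-wise OR across samples.
#'
#' @slot flags Logical matrix, rows = genes (named), columns = samples.
#'
#' @seealso [flagGenesByZcr()], [combineFlags()], [combinedFlags()]
#' @exportClass GeneFlagTable
setClass("GeneFlagTable", representation(flags = "matrix"))

setValidity("GeneFlagTable", function(object) {
  if (!is.logical(object@flags))
    return("flags must be a logical matrix")
  if (is.null(rownames(object@flags)) || is.null(colnames(object@flags)))
    return("flags must have gene rownames and sample colnames")
  TRUE
})

#' PresenceAbsenceMatrix: per-locus absence calls across samples
#'
#' For each named locus, the fraction of its bases covered by each
#' sample's ZCRs, and a binary absence call at a threshold fraction.
#'
#' @slot loci Named [GenomicRanges::GRanges] of loci.
#' @slot fraction Numeric matrix in \[0,1\], loci x samples.
#' @slot absent Logical matrix: `fraction >= threshold`.
#' @slot threshold Absence-call threshold on the covered fraction.
#'
#' @seealso [locusAbsenceMatrix()], [discordantLoci()],
#'   [complementaryPairs()]
#' @exportClass PresenceAbsenceMatrix
setClass("PresenceAbsenceMatrix",
  representation(loci = "GRanges", fraction = "matrix",
                 absent = "matrix", threshold = "numeric"))

setValidity("PresenceAbsenceMatrix", function(object) {
  if (is.null(names(object@loci)))
    return("loci must be named")
  if (!identical(dim(object@fraction), dim(object@absent)))
    return("fraction and absent must have identical dimensions")
  if (nrow(object@fraction) != length(object@loci))
    return("one matrix row per locus required")
  f <- object@fraction
  if (any(f < 0 | f > 1))
    return("fractions must lie in [0, 1]")
  if (!identical(object@absent, f >= object@threshold))
    return("absent must equal fraction >= threshold")
  TRUE
})
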