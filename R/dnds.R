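## Composite per-gene dN/dS from variant consequences on the canonical
## transcript. The statistic is a raw count ratio (non-synonymous /
## synonymous SNVs pooled across samples' alternate alleles), not a
## substitution-model estimate: no codon-frequency normalisation, no
## site or branch models.

## Spliced CDS sequence (CDS strand) and exon bookkeeping for one gene.
## Returns list(seq = DNAString on the coding strand, pieces = GRanges
## sorted by genomic start, cumw = cumulative piece widths before each
## piece, strand).
splicedCds <- function(catalog, seqs, gid) {
  pieces <- cdsRanges(catalog)[[gid]]
  st <- as.character(strand(geneRanges(catalog)[gid]))
  chr <- as.character(seqnames(geneRanges(catalog)[gid]))
  frag <- Biostrings::extractAt(seqs[[chr]], ranges(pieces))
  sq <- unlist(frag)
  if (st == "-") sq <- reverseComplement(sq)
  list(seq = sq, pieces = pieces,
       cumw = c(0L, cumsum(width(pieces))), strand = st, chrom = chr)
}

## genomic position -> 1-based position in the spliced CDS (CDS strand)
cdsPosition <- function(sc, pos) {
  i <- which(start(sc$pieces) <= pos & end(sc$pieces) >= pos)
  if (!length(i)) return(NA_integer_)
  plus_off <- sc$cumw[i] + (pos - start(sc$pieces)[i] + 1L)
  total <- sc$cumw[length(sc$cumw)]
  if (sc$strand == "+") plus_off else total - plus_off + 1L
}

#' Classify single-nucleotide variants by coding consequence
#'
#' For each allele lying in the canonical CDS of a gene, the spliced
#' CDS is built, the affected codon located (reverse-complementing for
#' minus-strand genes), both codons translated with the standard
#' genetic code, and the call made: identical amino acid (including
#' stop-to-stop) is `synonymous`; a changed amino acid, stop gain or
#' stop loss is `nonsynonymous`. Alleles outside any CDS, and indel
#' alleles, are `noncoding_or_other`.
#'
#' @param catalog A [GeneCatalog-class].
#' @param seqs A [Biostrings::DNAStringSet] of reference chromosome
#'   sequences, named by chromosome.
#' @param chrom,pos,ref,alt Parallel vectors describing decomposed
#'   alleles (1-based positions, bases on the genomic plus strand).
#' @return `data.frame` with one row per (allele, overlapped gene):
#'   columns `gene_id`, `transcript_id` (NA outside CDS), `chrom`,
#'   `pos`, `ref`, `alt`, `klass`.
#' @examples
#' # AAA -> AAG at the third codon position is synonymous (Lys)
#' @export
classifyConsequence <- function(catalog, seqs, chrom, pos, ref, alt) {
  stopifnot(is(catalog, "GeneCatalog"),
            length(chrom) == length(pos),
            length(pos) == length(ref), length(ref) == length(alt))
  n <- length(pos)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!is_snv))
    warning(sum(!is_snv),
            " indel/MNV allele(s) classified as noncoding_or_other")

  ## reference check against the genome sequence (batch per chrom)
  snv <- which(is_snv)
  for (cn in unique(chrom[snv])) {
    j <- snv[chrom[snv] == cn]
    base <- as.character(Biostrings::extractAt(
      seqs[[cn]], IRanges(pos[j], width = 1L)))
    bad <- which(base != ref[j])
    if (length(bad))
      stop("data-integrity error: ref allele '", ref[j[bad[1]]],
           "' at ", cn, ":", pos[j[bad[1]]],
           " does not match reference base '", base[bad[1]], "'")
  }

  allele_gr <- GRanges(chrom, IRanges(pos, width = 1L))
  cdsl <- cdsRanges(catalog)
  cds_ul <- unlist(cdsl, use.names = FALSE)
  cds_gene <- rep(names(cdsl), lengths(cdsl))
  ov <- findOverlaps(allele_gr[is_snv], cds_ul, ignore.strand = TRUE)
  snv_idx <- which(is_snv)
  hit_allele <- snv_idx[queryHits(ov)]
  hit_gene <- cds_gene[subjectHits(ov)]
  dup <- duplicated(paste(hit_allele, hit_gene))
  hit_allele <- hit_allele[!dup]; hit_gene <- hit_gene[!dup]

  rows <- data.frame(gene_id = NA_character_,
                     transcript_id = NA_character_,
                     chrom = chrom, pos = pos, ref = ref, alt = alt,
                     klass = "noncoding_or_other",
                     stringsAsFactors = FALSE)
  out <- rows[setdiff(seq_len(n), hit_allele), , drop = FALSE]

  if (length(hit_allele)) {
    code <- GENETIC_CODE
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    tx <- setNames(geneRanges(catalog)$transcript_id, geneIds(catalog))
    cds_cache <- list()
    h_klass <- character(length(hit_allele))
    for (k in seq_along(hit_allele)) {
      j <- hit_allele[k]; gid <- hit_gene[k]
      sc <- cds_cache[[gid]]
      if (is.null(sc)) {
        sc <- splicedCds(catalog, seqs, gid)
        cds_cache[[gid]] <- sc
      }
      cp <- cdsPosition(sc, pos[j])
      ci <- (cp - 1L) %/% 3L
      within <- (cp - 1L) %% 3L + 1L
      codon <- as.character(subseq(sc$seq, ci * 3L + 1L, ci * 3L + 3L))
      alt_cds <- if (sc$strand == "+") alt[j] else comp[[alt[j]]]
      mut <- codon
      substr(mut, within, within) <- alt_cds
      h_klass[k] <- if (code[[codon]] == code[[mut]]) "synonymous"
                    else "nonsynonymous"
    }
    out <- rbind(out, data.frame(
      gene_id = hit_gene, transcript_id = unname(tx[hit_gene]),
      chrom = chrom[hit_allele], pos = pos[hit_allele],
      ref = ref[hit_allele], alt = alt[hit_allele],
      klass = h_klass, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(match(out$chrom, names(seqs)), out$pos, out$alt), ,
      drop = FALSE]
}

#' Composite per-gene dN/dS counts
#'
#' Pools the distinct alternate alleles carried by at least one sample;
#' each distinct (chrom, pos, ref, alt) counts once per overlapped gene
#' regardless of how many samples carry it (set
#' `countPerSample = TRUE` to count per carrying sample instead).
#' Genes with `dS = 0` remain in the census but carry no ratio;
#' `pseudocount = TRUE` instead adds 1 to both counts before forming
#' ratios.
#'
#' @param x A (typically hard-filtered) [VariantTable-class].
#' @param catalog A [GeneCatalog-class].
#' @param seqs Reference [Biostrings::DNAStringSet].
#' @param countPerSample Count each allele once per carrying sample.
#' @param pseudocount Add 1 to dN and dS before forming ratios.
#' @return `data.frame` with columns `gene_id`, `dN`, `dS`, `ratio`
#'   (NA when undefined), `log10_ratio` (NA unless `dN > 0` and
#'   `dS > 0`), one row per gene with at least one classified coding
#'   SNV.
#' @export
countGeneDnDs <- function(x, catalog, seqs, countPerSample = FALSE,
                          pseudocount = FALSE) {
  stopifnot(is(x, "VariantTable"))
  rec <- variantRecords(x)
  gm <- genotypeCopies(x)
  carried_n <- if (ncol(gm)) rowSums(!is.na(gm) & gm >= 1L) else
    rep(1L, nrow(rec))
  sel <- rec$type == "SNV" & carried_n >= 1L
  rec <- rec[sel, , drop = FALSE]
  carried_n <- carried_n[sel]
  if (!nrow(rec))
    return(data.frame(gene_id = character(0), dN = integer(0),
                      dS = integer(0), ratio = numeric(0),
                      log10_ratio = numeric(0)))
  calls <- classifyConsequence(catalog, seqs, rec$chrom, rec$pos,
                               rec$ref, rec$alt)
  coding <- calls[!is.na(calls$gene_id) &
                  calls$klass %in% c("synonymous", "nonsynonymous"), ,
                  drop = FALSE]
  if (countPerSample) {
    key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt)
    ckey <- paste(coding$chrom, coding$pos, coding$ref, coding$alt)
    wt <- carried_n[match(ckey, key)]
  } else {
    wt <- rep(1L, nrow(coding))
  }
  aggregateDnDs(coding$gene_id, coding$klass, wt,
                pseudocount = pseudocount)
}

## shared aggregation for the internal classifier and the consequence-
## table ingest path
aggregateDnDs <- function(gene_id, klass, weight = 1L,
                          pseudocount = FALSE) {
  weight <- as.numeric(rep_len(weight, length(gene_id)))
  genes <- sort(unique(gene_id))
  dN <- vapply(genes, function(g)
    sum(weight[gene_id == g & klass == "nonsynonymous"]), 0)
  dS <- vapply(genes, function(g)
    sum(weight[gene_id == g & klass == "synonymous"]), 0)
  nN <- if (pseudocount) dN + 1 else dN
  nS <- if (pseudocount) dS + 1 else dS
  ratio <- ifelse(nS > 0, nN / nS, NA_real_)
  log10_ratio <- ifelse(!is.na(ratio) & ratio > 0, log10(ratio),
                        NA_real_)
  data.frame(gene_id = genes, dN = unname(dN), dS = unname(dS),
             ratio = unname(ratio), log10_ratio = unname(log10_ratio),
             stringsAsFactors = FALSE)
}

#' Positive-selection gene sets from dN/dS ratios
#'
#' @param dnds Output of [countGeneDnDs()].
#' @param threshold Genes with defined ratio strictly greater than this
#'   enter the positive set (default 1).
#' @param high Genes with defined ratio greater than or equal to this
#'   enter the high-ratio set (default 10, boundary inclusive).
#' @return List with character vectors `positive` and `high`.
#' @export
positiveSelectionSet <- function(dnds, threshold = 1, high = 10) {
  def <- !is.na(dnds$ratio)
  list(positive = dnds$gene_id[def & dnds$ratio > threshold],
       high = dnds$gene_id[def & dnds$ratio >= high])
}

#' Manhattan-plot-ready dN/dS table
#'
#' One row per gene with a defined, positive ratio: chromosome, gene
#' midpoint, gene id and log10(dN/dS) (neutral ratio 1 maps to 0).
#' Genes with `dN = 0` or `dS = 0` are excluded (log10 undefined).
#'
#' @param dnds Output of [countGeneDnDs()].
#' @param catalog A [GeneCatalog-class] supplying gene positions.
#' @return `data.frame` sorted by (chromosome order, midpoint) with
#'   columns `chrom`, `midpoint`, `gene_id`, `log10_ratio`.
#' @export
manhattanTable <- function(dnds, catalog) {
  keep <- dnds[!is.na(dnds$log10_ratio), , drop = FALSE]
  g <- geneRanges(catalog)[keep$gene_id]
  out <- data.frame(chrom = as.character(seqnames(g)),
                    midpoint = (start(g) + end(g)) %/% 2L,
                    gene_id = keep$gene_id,
                    log10_ratio = keep$log10_ratio,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, seqlevels(g)), out$midpoint), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default mapping of consequence terms to dN/dS classes
#'
#' Mirrors the conventional VEP-style vocabulary: missense, stop gain,
#' stop loss and start loss count as non-synonymous; synonymous and
#' stop-retained as synonymous. Editable and passed to
#' [readConsequenceTable()].
#'
#' @return Named character vector term -> class.
#' @export
defaultConsequenceMapping <- function() {
  c(missense_variant = "nonsynonymous",
    stop_gained = "nonsynonymous",
    stop_lost = "nonsynonymous",
    start_lost = "nonsynonymous",
    synonymous_variant = "synonymous",
    stop_retained_variant = "synonymous")
}

#' Ingest a consequence table in place of the internal classifier
#'
#' For real-data use where consequences were pre-computed by an
#' external annotator: reads a TSV of per-allele consequence terms,
#' maps terms to synonymous/non-synonymous and aggregates composite
#' per-gene counts. Terms absent from the mapping are ignored.
#'
#' @param path TSV with header columns `gene_id` and `consequence`
#'   (one row per distinct allele x gene).
#' @param mapping Named vector term -> class;
#'   [defaultConsequenceMapping()] by default.
#' @param pseudocount Passed through to the aggregation.
#' @return Same shape as [countGeneDnDs()].
#' @export
readConsequenceTable <- function(path,
                                 mapping = defaultConsequenceMapping(),
                                 pseudocount = FALSE) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "consequence") %in% names(df)))
    stop("consequence table needs 'gene_id' and 'consequence' columns")
  klass <- unname(mapping[df$consequence])
  keep <- !is.na(klass)
  aggregateDnDs(df$gene_id[keep], klass[keep],
                pseudocount = pseudocount)
}
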