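## Synthetic multi-sample study generator with planted truth. The
## defaults emulate the study design the package targets: deep
## resequencing of two clonal (almost entirely homozygous) individuals
## and one outbred (majority-heterozygous) individual against a single
## reference carrying a compact MHC-like gene cluster, a large NLR-like
## cluster filling 40% of one chromosome, assembly gaps, per-sample
## absent blocks (the coverage signature of deletion or divergence),
## and per-gene selection classes planted through codon-verified
## synonymous / non-synonymous variant counts.

#' Default configuration for the synthetic study
#'
#' Toy scale chosen so the full pipeline runs in seconds: three
#' chromosomes (2 Mb, 1 Mb, 0.5 Mb), 200 genes, three samples. Two
#' clonal samples are sequenced at 55x with a 3% heterozygous genotype
#' fraction; the outbred sample at 50x with 60% heterozygous calls.
#' Thirty genes are planted under positive selection (dN >> dS, most
#' of them inside the NLR-like cluster), 85 neutral and 85 purifying.
#'
#' @param ... Named overrides of any default element.
#' @return A configuration list.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    chromLengths = c(chr1 = 2000000L, chr2 = 1000000L,
                     chr4 = 500000L),
    nGenes = 200L,
    omegaCounts = c(positive = 30L, neutral = 85L, purifying = 85L),
    ## clusters: a compact MHC-like locus split into two adjacent
    ## sub-loci (the complementary-haplotype analog), and an NLR-like
    ## cluster spanning the distal 40% of chr4
    mhcChrom = "chr2", mhcStart = 400001L,
    mhcGenesPerSublocus = 7L,
    nlrChrom = "chr4", nlrStart = 300001L, nlrEnd = 500000L,
    nlrGenes = 50L,
    nGaps = 12L, gapWidth = c(1000L, 5000L),
    samples = list(
      list(sample_id = "CG1like", mean_depth = 55, het_fraction = 0.03,
           clonal = TRUE),
      list(sample_id = "CG2like", mean_depth = 55, het_fraction = 0.03,
           clonal = TRUE),
      list(sample_id = "AB3like", mean_depth = 50, het_fraction = 0.60,
           clonal = FALSE)),
    nlrBlocksPerSample = 3L, nlrBlockWidth = c(20000L, 50000L),
    backgroundBlocksPerSample = 6L,
    backgroundBlockWidth = c(3000L, 10000L),
    subThresholdBlocksPerSample = 2L,
    windowSize = 500L,
    noise = TRUE, noiseRate = 1e-3, noiseWidth = c(500L, 1500L),
    minZcrLength = 2000L,
    nNoncodingSnvs = 8000L, nIndels = 2000L, nArtifacts = 600L,
    carrierRate = 0.85,
    nRandomTerms = 10L, termSize = c(15L, 40L))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

## draw (dN, dS) targets for one gene of a given selection class
drawClassCounts <- function(klass) {
  switch(klass,
    positive = {
      dS <- 1L + rpois(1, 0.7)
      c(dN = dS + 1L + rpois(1, 6), dS = dS)
    },
    neutral = {
      dS <- 1L + rpois(1, 3)
      c(dN = rpois(1, dS), dS = dS)
    },
    purifying = c(dN = rpois(1, 1), dS = 2L + rpois(1, 6)))
}

## build one gene's CDS pieces / exons starting at genomic 'at'
## (coordinates relative to chromosome). Returns list(exons, cds, span)
buildGeneStructure <- function(at) {
  L <- 3L * sample(100:250, 1)           # CDS length 300-750, %% 3 == 0
  k <- sample(1:3, 1)                    # CDS pieces
  if (k == 1L) {
    widths <- L
  } else {
    cuts <- sort(sample(seq(30L, L - 30L, by = 3L), k - 1L))
    widths <- diff(c(0L, cuts, L))
  }
  introns <- if (k > 1L) sample(100:400, k - 1L, replace = TRUE)
             else integer(0)
  starts <- integer(k); p <- at
  for (i in seq_len(k)) {
    starts[i] <- p
    p <- p + widths[i] + if (i < k) introns[i] else 0L
  }
  cds <- IRanges(starts, width = widths)
  ex <- cds
  start(ex)[1] <- start(ex)[1] - 50L     # 5' UTR
  end(ex)[k] <- end(ex)[k] + 50L         # 3' UTR
  list(cds = cds, exons = ex,
       span = IRanges(min(start(ex)), max(end(ex))))
}

## place n genes left-to-right inside [from, to] on one chromosome,
## avoiding 'avoid' (IRanges); spacing drawn from spacingRange
placeGenes <- function(n, from, to, spacing, avoid = IRanges()) {
  out <- vector("list", n)
  p <- from
  for (i in seq_len(n)) {
    repeat {
      p <- p + sample(spacing[1]:spacing[2], 1)
      g <- buildGeneStructure(p + 50L)
      if (max(end(g$span)) > to)
        stop("configuration error: requested genes do not fit in ",
             "[", from, ",", to, "]")
      if (length(avoid) &&
          length(findOverlaps(g$span + 50L, avoid)) > 0) {
        ## skip past the offending region and retry
        hit <- subjectHits(findOverlaps(g$span + 50L, avoid))
        p <- max(end(avoid[hit]))
        next
      }
      out[[i]] <- g
      p <- max(end(g$span))
      break
    }
  }
  out
}

#' Generate the synthetic reference bundle
#'
#' Deterministic for a fixed seed: a genome layout with assembly gaps
#' (written as N runs in the FASTA), chromosome sequences, a gene
#' catalog in which every CDS length is divisible by 3, cluster gene
#' sets (MHC-like, NLR-like), per-gene selection classes, named MHC
#' sub-loci for haplotype-pattern analysis, and a gene-to-term map in
#' which the `immune_like` term is the union of the two clusters.
#'
#' @param config A list from [syntheticConfig()].
#' @param seed Integer master seed.
#' @return List with elements `layout`, `seqs`, `catalog`, `geneSets`,
#'   `geneClass`, `loci`, `termMap`.
#' @export
generateReference <- function(config = syntheticConfig(), seed = 1L) {
  withSeed(subSeed(seed, "reference"), {
    sl <- config$chromLengths
    ## --- assembly gaps, kept clear of the cluster regions
    cluster_regions <- grOn(
      c(config$mhcChrom, config$nlrChrom),
      IRanges(c(config$mhcStart, config$nlrStart),
              c(config$mhcStart + 100000L, config$nlrEnd)),
      names(sl))
    gaps <- grOn(character(0), IRanges(), names(sl))
    for (i in seq_len(config$nGaps)) {
      repeat {
        chr <- sample(names(sl), 1, prob = as.numeric(sl))
        w <- sample(config$gapWidth[1]:config$gapWidth[2], 1)
        st <- sample(seq_len(sl[[chr]] - w), 1)
        cand <- grOn(chr, IRanges(st, width = w), names(sl))
        if (!length(findOverlaps(cand + 2000L, cluster_regions)) &&
            !length(findOverlaps(cand + 2000L, gaps))) {
          gaps <- c(gaps, cand)
          break
        }
      }
    }
    gaps <- sort(gaps)
    layout <- GenomeLayout(sl, gaps)

    ## --- gene placement
    nBackground <- config$nGenes - 2L * config$mhcGenesPerSublocus -
      config$nlrGenes
    if (nBackground < 0L)
      stop("configuration error: cluster genes exceed nGenes")
    gap_by_chr <- split(ranges(gaps), as.character(seqnames(gaps)))

    avoid_for <- function(chr) {
      av <- if (chr %in% names(gap_by_chr)) gap_by_chr[[chr]]
            else IRanges()
      av
    }

    mhcA <- placeGenes(config$mhcGenesPerSublocus, config$mhcStart,
                       config$mhcStart + 49999L, c(200L, 800L),
                       avoid_for(config$mhcChrom))
    mhcA_end <- max(vapply(mhcA, function(g) max(end(g$span)), 0L))
    mhcB <- placeGenes(config$mhcGenesPerSublocus, mhcA_end + 3000L,
                       config$mhcStart + 119999L, c(200L, 800L),
                       avoid_for(config$mhcChrom))
    nlr <- placeGenes(config$nlrGenes, config$nlrStart,
                      config$nlrEnd, c(200L, 2000L),
                      avoid_for(config$nlrChrom))
    ## background genes on chr1 and the proximal part of chr2
    n_bg1 <- ceiling(nBackground * 2 / 3)
    bg1 <- placeGenes(n_bg1, 1000L, sl[["chr1"]] - 2000L,
                      c(2000L, 9000L), avoid_for("chr1"))
    bg2 <- placeGenes(nBackground - n_bg1, 1000L,
                      config$mhcStart - 5000L, c(2000L, 9000L),
                      avoid_for("chr2"))

    blocks <- list(
      list(chrom = config$mhcChrom, genes = mhcA, prefix = "mhcA"),
      list(chrom = config$mhcChrom, genes = mhcB, prefix = "mhcB"),
      list(chrom = config$nlrChrom, genes = nlr, prefix = "nlr"),
      list(chrom = "chr1", genes = bg1, prefix = "bg1"),
      list(chrom = "chr2", genes = bg2, prefix = "bg2"))

    g_chr <- character(0); g_id <- character(0)
    g_strand <- character(0); g_span <- IRanges()
    exl <- list(); cdl <- list()
    for (b in blocks) {
      for (i in seq_along(b$genes)) {
        gid <- sprintf("%s_g%03d", b$prefix, i)
        g <- b$genes[[i]]
        g_chr <- c(g_chr, b$chrom); g_id <- c(g_id, gid)
        g_strand <- c(g_strand, sample(c("+", "-"), 1))
        g_span <- c(g_span, g$span)
        exl[[gid]] <- grOn(b$chrom, g$exons, names(sl))
        cdl[[gid]] <- grOn(b$chrom, g$cds, names(sl))
      }
    }
    gene_gr <- grOn(g_chr, g_span, names(sl), strand = g_strand)
    names(gene_gr) <- g_id
    gene_gr$gene_id <- g_id
    gene_gr$transcript_id <- paste0(g_id, ".t1")
    catalog <- GeneCatalog(gene_gr, GRangesList(exl), GRangesList(cdl))

    ## --- selection classes: 2/3 of positive genes inside the NLR
    ## cluster (the chromosome-arm signal), the rest at random
    ids <- geneIds(catalog)
    nlr_ids <- grep("^nlr_", ids, value = TRUE)
    n_pos <- config$omegaCounts[["positive"]]
    n_pos_nlr <- min(round(n_pos * 2 / 3), length(nlr_ids))
    pos_ids <- c(sample(nlr_ids, n_pos_nlr),
                 sample(setdiff(ids, nlr_ids), n_pos - n_pos_nlr))
    rest <- setdiff(ids, pos_ids)
    neu_ids <- sample(rest, config$omegaCounts[["neutral"]])
    pur_ids <- setdiff(rest, neu_ids)
    if (length(pur_ids) != config$omegaCounts[["purifying"]])
      stop("configuration error: omegaCounts must sum to nGenes")
    geneClass <- setNames(rep("purifying", length(ids)), ids)
    geneClass[pos_ids] <- "positive"
    geneClass[neu_ids] <- "neutral"

    ## --- sequences with N runs over gaps
    seqs <- DNAStringSet(vapply(names(sl), function(chr)
      randomDna(sl[[chr]]), ""))
    names(seqs) <- names(sl)
    for (i in seq_along(gaps)) {
      chr <- as.character(seqnames(gaps)[i])
      subseq(seqs[[chr]], start(gaps)[i], end(gaps)[i]) <-
        DNAString(paste(rep("N", width(gaps)[i]), collapse = ""))
    }

    ## --- gene sets, loci, term map
    mhc_ids <- grep("^mhc", ids, value = TRUE)
    geneSets <- list(MHC_like = mhc_ids, NLR_like = nlr_ids)
    span_of <- function(prefix) {
      g <- geneRanges(catalog)[grep(prefix, ids)]
      GRanges(as.character(seqnames(g)[1]),
              IRanges(min(start(g)), max(end(g))))
    }
    loci <- c(span_of("^mhcA_"), span_of("^mhcB_"))
    names(loci) <- c("mhcA_locus", "mhcB_locus")

    termMap <- list(immune_like = c(mhc_ids, nlr_ids))
    for (t in seq_len(config$nRandomTerms)) {
      sz <- sample(config$termSize[1]:config$termSize[2], 1)
      termMap[[sprintf("term%02d", t)]] <- sample(ids, sz)
    }

    list(layout = layout, seqs = seqs, catalog = catalog,
         geneSets = geneSets, geneClass = geneClass, loci = loci,
         termMap = termMap)
  })
}
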