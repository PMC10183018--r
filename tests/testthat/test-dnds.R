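# Codon-aware consequence classification and composite dN/dS.

# a one-gene catalog whose CDS is `cds_seq` placed at `at` on a random
# background; minus-strand genes carry the reverse complement in the
# genome so the CDS reads `cds_seq`
codonFixture <- function(cds_seq, strand = "+", at = 101L) {
  n <- nchar(cds_seq)
  genomic <- if (strand == "+") cds_seq else
    as.character(reverseComplement(DNAString(cds_seq)))
  set.seed(5)
  left <- paste(sample(c("A", "C", "G", "T"), at - 1, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
  seqs <- DNAStringSet(setNames(paste0(left, genomic, right), "chr"))
  g <- GRanges("chr", IRanges(at, at + n - 1L), strand = strand)
  names(g) <- "g"
  g$gene_id <- "g"
  g$transcript_id <- "g.t1"
  catalog <- GeneCatalog(g, GRangesList(g = granges(g)),
                         GRangesList(g = granges(g)))
  list(catalog = catalog, seqs = seqs, at = at)
}

test_that("synonymous and non-synonymous substitutions on the plus strand", {
  fx <- codonFixture("AAA")
  # third position AAA->AAG: Lys->Lys
  syn <- classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at + 2L,
                             "A", "G")
  expect_equal(syn$klass, "synonymous")
  # first position AAA->GAA: Lys->Glu
  non <- classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at,
                             "A", "G")
  expect_equal(non$klass, "nonsynonymous")
})

test_that("minus-strand substitutions are evaluated on the coding strand", {
  # CDS codon AAA on the minus strand: genome reads TTT; a genomic
  # T->C at the first genomic base hits the third CDS position
  fx <- codonFixture("AAA", strand = "-")
  # genomic position at+2 is CDS position 1; T->C => CDS G.. => GAA
  call <- classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at + 2L,
                              "T", "C")
  expect_equal(call$klass, "nonsynonymous")   # Lys -> Glu
  # genomic position at is CDS position 3; T->C => AAG, synonymous
  call2 <- classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at,
                               "T", "C")
  expect_equal(call2$klass, "synonymous")
})

test_that("stop gain counts as non-synonymous; stop retained as synonymous", {
  fx <- codonFixture("TAC")
  gained <- classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at + 2L,
                                "C", "A")   # TAC -> TAA
  expect_equal(gained$klass, "nonsynonymous")
  fx2 <- codonFixture("TAA")
  retained <- classifyConsequence(fx2$catalog, fx2$seqs, "chr",
                                  fx2$at + 2L, "A", "G")  # TAA -> TAG
  expect_equal(retained$klass, "synonymous")
})

test_that("reference mismatches error; indels and non-CDS positions are other", {
  fx <- codonFixture("AAA")
  expect_error(classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at,
                                   "C", "G"),
               "data-integrity")
  expect_warning(
    ind <- classifyConsequence(fx$catalog, fx$seqs, "chr", fx$at,
                               "AA", "A"),
    "indel")
  expect_equal(ind$klass, "noncoding_or_other")
  out <- classifyConsequence(fx$catalog, fx$seqs, "chr", 5L,
                             as.character(subseq(fx$seqs[["chr"]], 5, 5)),
                             "A")
  expect_true(is.na(out$gene_id) || out$klass == "noncoding_or_other")
})

test_that("classifier agrees with a translate-both-codons oracle over all 576 substitutions, both strands", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                  collapse = "")
  oracle <- function(codon, within, altb) {
    mut <- codon
    substr(mut, within, within) <- altb
    aa1 <- seqinr::translate(seqinr::s2c(codon))
    aa2 <- seqinr::translate(seqinr::s2c(mut))
    if (identical(aa1, aa2)) "synonymous" else "nonsynonymous"
  }
  for (st in c("+", "-")) {
    # one genome per strand: 64 single-codon genes, spaced 10 bp apart
    gene_at <- 101L + (seq_along(codons) - 1L) * 13L
    genomic <- vapply(codons, function(cd)
      if (st == "+") cd else
        as.character(reverseComplement(DNAString(cd))), "")
    set.seed(6)
    backbone <- rep("ACGTACGTAC", length(codons))
    chrseq <- paste0(paste0(backbone, genomic, collapse = ""), "ACG")
    # reposition: codon i occupies gene_at[i] .. gene_at[i]+2
    gene_at <- 11L + (seq_along(codons) - 1L) * 13L
    seqs <- DNAStringSet(setNames(chrseq, "chr"))
    g <- GRanges("chr", IRanges(gene_at, gene_at + 2L), strand = st)
    names(g) <- sprintf("g%02d", seq_along(codons))
    g$gene_id <- names(g)
    g$transcript_id <- paste0(names(g), ".t1")
    catalog <- GeneCatalog(
      g, setNames(GRangesList(as.list(split(granges(g), names(g)))[names(g)]),
                  names(g)),
      setNames(GRangesList(as.list(split(granges(g), names(g)))[names(g)]),
               names(g)))

    # build every substitution in genomic coordinates
    chrom <- character(0); pos <- integer(0)
    refv <- character(0); altv <- character(0)
    expected <- character(0)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (i in seq_along(codons)) {
      for (within in 1:3) {
        refb_cds <- substr(codons[i], within, within)
        gpos <- if (st == "+") gene_at[i] + within - 1L
                else gene_at[i] + 3L - within
        refb_gen <- if (st == "+") refb_cds else comp[[refb_cds]]
        for (altb_cds in setdiff(bases, refb_cds)) {
          chrom <- c(chrom, "chr"); pos <- c(pos, gpos)
          refv <- c(refv, refb_gen)
          altv <- c(altv, if (st == "+") altb_cds else comp[[altb_cds]])
          expected <- c(expected, oracle(codons[i], within, altb_cds))
        }
      }
    }
    calls <- classifyConsequence(catalog, seqs, chrom, pos, refv, altv)
    key <- paste(calls$pos, calls$alt)
    got <- setNames(calls$klass, key)[paste(pos, altv)]
    expect_equal(unname(got), expected,
                 label = paste("strand", st, "classifications"))
    expect_length(got, 576L)
  }
})

test_that("composite counts pool distinct alleles once across samples", {
  fx <- codonFixture("AAAGGGTTTCCC")
  rec <- data.frame(chrom = "chr",
                    pos = fx$at + c(0L, 2L, 5L, 8L),
                    ref = c("A", "A", "G", "T"),
                    alt = c("G", "G", "A", "A"),
                    stringsAsFactors = FALSE)
  rec$type <- "SNV"
  # allele 1 carried by all three samples; the rest by one each
  gt <- rbind(c(2L, 2L, 2L), c(2L, 0L, 0L), c(0L, 1L, 0L),
              c(0L, 0L, 2L))
  colnames(gt) <- c("s1", "s2", "s3")
  x <- new("VariantTable", records = rec,
           info = as.data.frame(matrix(nrow = 4, ncol = 0)),
           genotypes = gt)
  d <- countGeneDnDs(x, fx$catalog, fx$seqs)
  # AAA->GAA (nonsyn), AAA->AAG (syn), GGG->GAG... positions: pos+5 is
  # third G of GGG? recompute: GGG spans at+3..at+5; pos+5 third base
  # G->A: GGG->GGA synonymous; TTT at+6..at+8: pos+8 third T->A:
  # TTT->TTA nonsynonymous (Phe->Leu)
  expect_equal(d$dN, 2)
  expect_equal(d$dS, 2)
  expect_equal(d$ratio, 1.0)

  # per-sample occurrence counting weights the shared allele three-fold
  d2 <- countGeneDnDs(x, fx$catalog, fx$seqs, countPerSample = TRUE)
  expect_equal(d2$dN, 4)   # shared nonsyn allele counts 3, plus TTA
  expect_equal(d2$dS, 2)
})

test_that("genes with dS = 0 keep counts but no ratio; pseudocount mode defines one", {
  d <- aggregateDnDs(c("g", "g"), c("nonsynonymous", "nonsynonymous"))
  expect_equal(d$dN, 2)
  expect_true(is.na(d$ratio))
  dp <- aggregateDnDs(c("g", "g"), c("nonsynonymous", "nonsynonymous"),
                      pseudocount = TRUE)
  expect_equal(dp$ratio, 3)
})

test_that("positive-selection thresholds: strict at 1, inclusive at 10", {
  d <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  dN = c(3, 1, 2, 10), dS = c(1, 2, 2, 1),
                  ratio = c(3, 0.5, 1, 10),
                  log10_ratio = log10(c(3, 0.5, 1, 10)))
  s <- positiveSelectionSet(d)
  expect_equal(s$positive, c("g1", "g4"))
  expect_equal(s$high, "g4")
  none <- positiveSelectionSet(d[0, ])
  expect_length(none$positive, 0L)
  expect_length(none$high, 0L)
})

test_that("Manhattan rows carry log10 ratios sorted by position; undefined ratios drop", {
  study <- cachedTinyStudy()
  filtered <- hardFilter(study$variants$table)
  d <- countGeneDnDs(filtered, study$reference$catalog,
                     study$reference$seqs)
  m <- manhattanTable(d, study$reference$catalog)
  expect_true(all(is.finite(m$log10_ratio)))
  expect_false(any(is.na(m$log10_ratio)))
  # neutral ratio 1 maps to zero; spot value log10(3)
  expect_equal(unique(m$log10_ratio[abs(m$log10_ratio) < 1e-12]),
               numeric(if (any(abs(m$log10_ratio) < 1e-12)) 1 else 0))
  # sorted within chromosome by midpoint
  for (cn in unique(m$chrom))
    expect_false(is.unsorted(m$midpoint[m$chrom == cn]))
  expect_equal(round(log10(3), 4), 0.4771)
})

test_that("consequence-table ingest matches the internal classifier's aggregation", {
  study <- cachedTinyStudy()
  tr <- study$variants$truth
  gm <- genotypeCopies(study$variants$table)
  rec <- variantRecords(study$variants$table)
  carried_key <- paste(rec$chrom, rec$pos, rec$alt)[
    rowSums(!is.na(gm) & gm >= 1L) > 0L]
  coding <- tr[tr$klass %in% c("synonymous", "nonsynonymous") &
                 paste(tr$chrom, tr$pos, tr$alt) %in% carried_key, ]
  tsv <- tempfile(fileext = ".tsv")
  write.table(
    data.frame(gene_id = coding$gene_id,
               consequence = ifelse(coding$klass == "synonymous",
                                    "synonymous_variant",
                                    "missense_variant")),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ing <- readConsequenceTable(tsv)
  # classifier route on the same (unfiltered) alleles
  x <- study$variants$table
  d <- countGeneDnDs(x, study$reference$catalog, study$reference$seqs)
  merged <- merge(ing, d, by = "gene_id")
  expect_equal(merged$dN.x, merged$dN.y)
  expect_equal(merged$dS.x, merged$dS.y)
})

test_that("planted positive-selection genes are recovered with strong enrichment", {
  study <- cachedStudy(seed = 101L, noise = FALSE)
  filtered <- hardFilter(study$variants$table)
  d <- countGeneDnDs(filtered, study$reference$catalog,
                     study$reference$seqs)
  sel <- positiveSelectionSet(d)$positive
  planted <- names(study$reference$geneClass)[
    study$reference$geneClass == "positive"]
  N <- length(study$reference$geneClass)
  k <- length(intersect(sel, planted))
  p <- phyper(k - 1, length(planted), N - length(planted),
              length(sel), lower.tail = FALSE)
  expect_lt(p, 1e-6)
})
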