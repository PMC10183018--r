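# The synthetic study generator: determinism, construction guarantees,
# coverage statistics and planted-truth self-consistency.

test_that("the generator is deterministic for a fixed seed", {
  cfg <- tinyConfig()
  r1 <- generateReference(cfg, seed = 9L)
  r2 <- generateReference(cfg, seed = 9L)
  expect_identical(as.character(r1$seqs), as.character(r2$seqs))
  expect_identical(geneRanges(r1$catalog), geneRanges(r2$catalog))
  expect_identical(r1$geneClass, r2$geneClass)

  p1 <- generateProfiles(r1, cfg, seed = 9L)
  p2 <- generateProfiles(r2, cfg, seed = 9L)
  expect_identical(p1[[1]]$absent, p2[[1]]$absent)

  v1 <- simulateVariants(r1, p1, cfg, seed = 9L)
  v2 <- simulateVariants(r2, p2, cfg, seed = 9L)
  expect_identical(variantRecords(v1$table), variantRecords(v2$table))
  expect_identical(genotypeCopies(v1$table), genotypeCopies(v2$table))

  t1 <- simulateSampleCoverage(r1$layout, p1[[1]], cfg, seed = 9L)
  t2 <- simulateSampleCoverage(r2$layout, p2[[1]], cfg, seed = 9L)
  expect_identical(coverageRle(t1), coverageRle(t2))
})

test_that("the reference honours its configuration: gene count, CDS framing, cluster placement", {
  study <- cachedTinyStudy()
  ref <- study$reference
  cfg <- tinyConfig()
  expect_length(geneIds(ref$catalog), cfg$nGenes)
  expect_true(all(sum(width(cdsRanges(ref$catalog))) %% 3 == 0))
  # every cluster gene lies inside its cluster interval
  nlr_span <- GRanges(cfg$nlrChrom, IRanges(cfg$nlrStart, cfg$nlrEnd))
  nlr_genes <- geneRanges(ref$catalog)[ref$geneSets$NLR_like]
  expect_length(ref$geneSets$NLR_like, cfg$nlrGenes)
  expect_true(all(overlapsAny(nlr_genes, nlr_span, type = "within")))
  # class counts match the configuration
  expect_equal(unname(table(ref$geneClass)[c("positive", "neutral",
                                             "purifying")]),
               unname(cfg$omegaCounts), ignore_attr = TRUE)
  # gaps are written as N runs in the FASTA
  gaps <- assemblyGaps(ref$layout)
  g1 <- gaps[1]
  run <- subseq(ref$seqs[[as.character(seqnames(g1))]],
                start(g1), end(g1))
  expect_equal(as.character(unique(strsplit(as.character(run),
                                            "")[[1]])), "N")
})

test_that("simulated depth is Poisson-like around the profile mean outside absent blocks", {
  study <- cachedTinyStudy()
  prof <- study$profiles[[1]]
  cov <- coverageRle(study$tracks[[1]])[["chr1"]]
  # restrict to a 100 kb window away from this sample's absent blocks
  win <- GRanges("chr1", IRanges(1, 100000))
  hits <- findOverlaps(win, prof$absent, ignore.strand = TRUE)
  clear <- setdiff(win, prof$absent[subjectHits(hits)],
                   ignore.strand = TRUE)
  vals <- unlist(lapply(seq_along(clear), function(i)
    as.integer(cov[start(clear)[i]:end(clear)[i]])))
  # depth is piecewise-constant over 500 bp windows, so the effective
  # number of independent Poisson draws is the window count
  n_draws <- length(vals) / 500
  se <- sqrt(prof$mean_depth / n_draws)
  expect_lt(abs(mean(vals) - prof$mean_depth), 3 * se)
})

test_that("absent blocks drive depth to zero; without them no qualifying zero runs arise", {
  study <- cachedTinyStudy()
  prof <- study$profiles[[1]]
  cov <- coverageRle(study$tracks[[1]])
  for (i in head(seq_along(prof$absent), 5)) {
    chr <- as.character(seqnames(prof$absent)[i])
    seg <- cov[[chr]][start(prof$absent)[i]:end(prof$absent)[i]]
    expect_true(all(runValue(seg) == 0))
  }
  # a profile with no absent blocks and noise off yields no zero run
  # at all at this depth (per-base scan)
  clean <- list(sample_id = "clean", mean_depth = 50,
                het_fraction = 0, clonal = TRUE,
                absent = GRanges())
  tr <- simulateSampleCoverage(study$reference$layout, clean,
                               tinyConfig(), seed = 33L)
  for (chr in names(coverageRle(tr))) {
    r <- coverageRle(tr)[[chr]]
    zero_runs <- runLength(r)[runValue(r) == 0]
    expect_true(length(zero_runs) == 0 || max(zero_runs) < 2000)
  }
})

test_that("clonal heterozygous fractions stay inside binomial 99% bounds", {
  study <- cachedTinyStudy()
  gm <- genotypeCopies(study$variants$table)
  for (p in study$profiles) {
    g <- gm[, p$sample_id]
    n <- sum(!is.na(g) & g >= 1L)
    k <- sum(g == 1L, na.rm = TRUE)
    expect_gte(k, qbinom(0.005, n, p$het_fraction))
    expect_lte(k, qbinom(0.995, n, p$het_fraction))
  }
})

test_that("planted coding variants reclassify to their planted class exactly", {
  study <- cachedTinyStudy()
  tr <- study$variants$truth
  coding <- tr[tr$klass %in% c("synonymous", "nonsynonymous"), ]
  calls <- classifyConsequence(study$reference$catalog,
                               study$reference$seqs,
                               coding$chrom, coding$pos,
                               coding$ref, coding$alt)
  m <- merge(coding, calls, by = c("chrom", "pos", "ref", "alt"))
  expect_equal(nrow(m), nrow(coding))
  expect_true(all(m$klass.x == m$klass.y))
  expect_true(all(m$gene_id.x == m$gene_id.y))
})

test_that("every emitted file parses back cleanly with no warnings", {
  dir <- file.path(tempdir(), "studyfiles")
  study <- generateStudy(tinyConfig(), seed = 17L, dir = dir)
  f <- study$files
  expect_no_warning({
    seqs <- readDNAStringSet(f$fasta)
    catalog <- readGff3Genes(f$gff3)
    sz <- read.table(f$sizes, col.names = c("chrom", "length"))
    layout <- GenomeLayout(setNames(sz$length, sz$chrom),
                           readBedIntervals(f$gaps))
    tabs <- readVariants(f$vcf)
    sets <- readGeneSets(f$gene_sets)
    terms <- readTermMap(f$term_map)
    tracks <- lapply(names(study$tracks), function(sid)
      readBedGraph(f[[paste0("bedgraph_", sid)]], layout, sid))
  })
  expect_equal(sum(width(seqs)), sum(chromLengths(layout)))
  expect_equal(geneIds(catalog), geneIds(study$reference$catalog))
  expect_equal(nrow(variantRecords(tabs)),
               nrow(variantRecords(study$variants$table)))
  # a read-back track reproduces the simulated coverage (bedGraph
  # scores come back numeric; depths themselves are unchanged)
  expect_equal(lapply(coverageRle(tracks[[1]]), as.integer),
               lapply(coverageRle(study$tracks[[1]]), as.integer))
})
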