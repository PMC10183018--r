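# Zero-coverage region detection against a literal per-base oracle.

trackFrom <- function(layout, score_gr, sid = "s") {
  CoverageTrack(score_gr, layout, sid)
}

test_that("no ZCRs when depth is positive everywhere; whole chromosome when empty", {
  layout <- GenomeLayout(c(chr = 10000L))
  full <- trackFrom(layout, GRanges("chr", IRanges(1, 10000), score = 3))
  expect_length(zcrRanges(detectZcrs(full, layout)), 0L)

  none <- trackFrom(layout, GRanges("chr", IRanges(1, 10000), score = 0))
  z <- zcrRanges(detectZcrs(none, layout))
  expect_equal(start(z), 1L)
  expect_equal(end(z), 10000L)
})

test_that("runs shorter than minLength are dropped, 2 kb boundary inclusive", {
  layout <- GenomeLayout(c(chr = 10000L))
  # zero runs 1001-3500 (2500 bp) and 4001-5900 (1900 bp)
  cov <- GRanges("chr", IRanges(c(1, 3501, 5901), c(1000, 4000, 10000)),
                 score = 5)
  z <- zcrRanges(detectZcrs(trackFrom(layout, cov), layout, 2000L))
  expect_equal(as.data.frame(ranges(z))[, c("start", "end")],
               data.frame(start = 1001L, end = 3500L))

  # a run of exactly 2000 bases qualifies
  cov2 <- GRanges("chr", IRanges(c(1, 3001), c(1000, 10000)), score = 5)
  z2 <- zcrRanges(detectZcrs(trackFrom(layout, cov2), layout, 2000L))
  expect_equal(width(z2), 2000L)
})

test_that("assembly gaps terminate runs and never bridge them by default", {
  # zero over 1001-4000, gap 2001-2500: sub-runs of 1000 and 1500 bp
  layout <- GenomeLayout(c(chr = 10000L),
                         GRanges("chr", IRanges(2001, 2500)))
  cov <- GRanges("chr", IRanges(c(1, 4001), c(1000, 10000)), score = 8)
  track <- trackFrom(layout, cov)
  expect_length(zcrRanges(detectZcrs(track, layout, 2000L)), 0L)

  # with bridging, the run qualifies on its 2500 non-gap zero bases and
  # is reported as the two gap-flanking pieces
  zb <- zcrRanges(detectZcrs(track, layout, 2000L, bridgeGaps = TRUE))
  expect_equal(start(zb), c(1001L, 2501L))
  expect_equal(end(zb), c(2000L, 4000L))
})

test_that("detectZcrs validates arguments", {
  layout <- GenomeLayout(c(chr = 10000L))
  track <- trackFrom(layout, GRanges("chr", IRanges(1, 10000), score = 1))
  expect_error(detectZcrs(track, layout, 0L), "positive")
  other <- GenomeLayout(c(other = 5000L))
  expect_error(detectZcrs(track, other, 2000L), "absent from layout")
})

test_that("detectZcrs equals the per-base oracle scan on random tracks", {
  set.seed(7)
  for (i in 1:120) {
    fix <- randomTrackFixture(sample(5000:20000, 1))
    min_len <- sample(c(500L, 1000L, 2000L), 1)
    z <- zcrRanges(detectZcrs(fix$track, fix$layout, min_len))
    expected <- zcrOracleScan(fix$depth, fix$gap, min_len)
    expect_equal(cbind(start = start(z), end = end(z)), expected,
                 ignore_attr = TRUE)
  }
})

test_that("raising minLength never adds intervals and nests reported sets", {
  set.seed(8)
  for (i in 1:25) {
    fix <- randomTrackFixture(12000L)
    lens <- c(300L, 800L, 1500L, 3000L)
    sets <- lapply(lens, function(L)
      zcrRanges(detectZcrs(fix$track, fix$layout, L)))
    for (k in seq_len(length(lens) - 1L)) {
      larger <- sets[[k + 1L]]; smaller <- sets[[k]]
      expect_lte(length(larger), length(smaller))
      if (length(larger))
        # every interval at the stricter threshold is also reported,
        # identically, at the looser one
        expect_true(all(as.character(larger) %in%
                        as.character(smaller)))
    }
  }
})

test_that("planted absent blocks are recovered with exact boundaries when noise is off", {
  study <- cachedStudy(seed = 101L, noise = FALSE)
  layout <- study$reference$layout
  for (sid in names(study$tracks)) {
    z <- detectZcrs(study$tracks[[sid]], layout, 2000L)
    truth <- study$profiles[[sid]]$zcr_truth
    expect_identical(granges(zcrRanges(z)), granges(truth))
  }
})

test_that("genome ZCR fraction with full and non-gap denominators", {
  layout <- GenomeLayout(c(chr = 1000000L))
  z <- new("ZCRSet", sampleId = "s",
           intervals = GRanges("chr", IRanges(1, 20000)),
           minLength = 2000L)
  expect_equal(genomeZcrFraction(z, layout), 2.0)

  empty <- new("ZCRSet", sampleId = "s", intervals = GRanges(),
               minLength = 2000L)
  expect_equal(genomeZcrFraction(empty, layout), 0.0)

  gapped <- GenomeLayout(c(chr = 1000000L),
                         GRanges("chr", IRanges(500001, 700000)))
  expect_equal(genomeZcrFraction(z, gapped, denominator = "nongap"),
               100 * 20000 / 800000)
})
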