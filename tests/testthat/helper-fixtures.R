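# Shared fixtures. Studies are cached per (seed, noise) so expensive
# generation runs once per test session.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

.study_cache <- new.env(parent = emptyenv())

cachedStudy <- function(seed = 101L, noise = TRUE) {
  key <- paste0("seed", seed, "_noise", noise)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- generateStudy(syntheticConfig(noise = noise),
                                         seed = seed)
  .study_cache[[key]]
}

# down-scaled configuration for tests that only need structure, not
# the full study conditions
tinyConfig <- function(...) {
  syntheticConfig(
    chromLengths = c(chr1 = 300000L, chr2 = 200000L, chr4 = 100000L),
    nGenes = 40L,
    omegaCounts = c(positive = 6L, neutral = 17L, purifying = 17L),
    mhcStart = 80001L, mhcGenesPerSublocus = 4L,
    nlrStart = 60001L, nlrEnd = 100000L, nlrGenes = 10L,
    nGaps = 4L,
    nlrBlocksPerSample = 2L, nlrBlockWidth = c(5000L, 12000L),
    backgroundBlocksPerSample = 3L,
    nNoncodingSnvs = 600L, nIndels = 150L, nArtifacts = 60L,
    noise = FALSE,
    ...)
}

cachedTinyStudy <- function(seed = 202L) {
  key <- paste0("tiny", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- generateStudy(tinyConfig(), seed = seed)
  .study_cache[[key]]
}

# independent per-base ZCR oracle: literal scan over depth and gap
# vectors (1-based), returning a matrix of [start, end] rows
zcrOracleScan <- function(depth, gap, minLen) {
  zero <- depth == 0 & !gap
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  cbind(start = starts[keep], end = ends[keep])
}

# random single-chromosome coverage fixture for oracle comparisons
randomTrackFixture <- function(len = 10000L) {
  n_gap <- sample(0:3, 1)
  gaps <- IRanges()
  if (n_gap > 0) {
    st <- sample.int(len - 500L, n_gap)
    gaps <- reduce(IRanges(st, width = sample(50:800, n_gap,
                                              replace = TRUE)))
    gaps <- restrict(gaps, 1L, len)
  }
  layout <- GenomeLayout(c(chrT = len),
                         GRanges(rep("chrT", length(gaps)), gaps))
  # depth: blocks of random depth including frequent zero runs
  n_seg <- sample(5:20, 1)
  bounds <- sort(sample.int(len - 1L, n_seg - 1L))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, len)
  depth <- sample(c(0L, 0L, 1L, 3L, 10L), n_seg, replace = TRUE)
  cov <- Rle(rep(depth, ends - starts + 1L))
  track <- new("CoverageTrack", sampleId = "rnd",
               coverage = RleList(chrT = cov, compress = FALSE),
               seqinfo = seqinfo(layout))
  gapvec <- rep(FALSE, len)
  for (i in seq_along(gaps))
    gapvec[start(gaps)[i]:end(gaps)[i]] <- TRUE
  list(layout = layout, track = track,
       depth = as.integer(cov), gap = gapvec)
}

# write lines to a temp file, return path
tmpfile <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
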