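#' Generate per-sample profiles with planted absent blocks
#'
#' Each sample receives: its cluster-level haplotype pattern (the MHC-A
#' sub-locus is absent in the outbred sample only; the MHC-B sub-locus
#' is absent in both clonal samples — the complementary pattern of two
#' alternative haplotypes assembled in tandem in the reference), a set
#' of large random absent blocks inside the NLR-like cluster, random
#' background blocks genome-wide, and a few sub-threshold (< 2 kb)
#' blocks that must *not* be reported as ZCRs.
#'
#' @param reference Output of [generateReference()].
#' @param config,seed As in [generateReference()].
#' @return Named list of profiles; each has `sample_id`, `mean_depth`,
#'   `het_fraction`, `clonal`, `absent` (a [GenomicRanges::GRanges]),
#'   and `zcr_truth` (non-gap sub-runs of the absent blocks at least
#'   `config$minZcrLength` long — the expected ZCR calls with noise
#'   off).
#' @export
generateProfiles <- function(reference, config = syntheticConfig(),
                             seed = 1L) {
  sl <- chromLengths(reference$layout)
  gaps <- assemblyGaps(reference$layout)
  loci <- reference$loci
  profiles <- list()
  for (sp in config$samples) {
    sid <- sp$sample_id
    profiles[[sid]] <- withSeed(subSeed(seed, "profile", sid), {
      mhc <- if (sp$clonal) loci["mhcB_locus"] else loci["mhcA_locus"]
      ## complementary MHC pattern: pad so the whole sub-locus
      ## (fraction 1 of each gene span) is covered
      b_chr <- as.character(seqnames(mhc))
      b_rng <- ranges(mhc) + 1000L
      ## large blocks inside the NLR-like cluster
      for (i in seq_len(config$nlrBlocksPerSample)) {
        w <- sample(config$nlrBlockWidth[1]:config$nlrBlockWidth[2], 1)
        st <- sample(seq(config$nlrStart, config$nlrEnd - w), 1)
        b_chr <- c(b_chr, config$nlrChrom)
        b_rng <- c(b_rng, IRanges(st, width = w))
      }
      ## background blocks anywhere
      for (i in seq_len(config$backgroundBlocksPerSample)) {
        chr <- sample(names(sl), 1, prob = as.numeric(sl))
        w <- sample(config$backgroundBlockWidth[1]:
                      config$backgroundBlockWidth[2], 1)
        st <- sample(seq_len(sl[[chr]] - w), 1)
        b_chr <- c(b_chr, chr)
        b_rng <- c(b_rng, IRanges(st, width = w))
      }
      ## sub-threshold blocks: too short to qualify as ZCRs
      for (i in seq_len(config$subThresholdBlocksPerSample)) {
        chr <- sample(names(sl), 1, prob = as.numeric(sl))
        w <- sample(800:1500, 1)
        st <- sample(seq_len(sl[[chr]] - w), 1)
        b_chr <- c(b_chr, chr)
        b_rng <- c(b_rng, IRanges(st, width = w))
      }
      names(b_rng) <- NULL
      blocks <- reduce(sort(grOn(b_chr, b_rng, names(sl))))
      if (any(end(blocks) > sl[as.character(seqnames(blocks))]))
        stop("absent block outside chromosome")
      truth <- setdiff(blocks, gaps, ignore.strand = TRUE)
      truth <- truth[width(truth) >= config$minZcrLength]
      list(sample_id = sid, mean_depth = sp$mean_depth,
           het_fraction = sp$het_fraction, clonal = sp$clonal,
           absent = blocks, zcr_truth = sort(truth))
    })
  }
  profiles
}

#' Simulate one sample's coverage track
#'
#' Depth is piecewise-constant over windows, drawn Poisson around the
#' profile's mean depth; absent blocks are forced to depth zero. With
#' `config$noise`, short zero runs (shorter than the ZCR minimum
#' length) are scattered at rate `noiseRate` per window to exercise
#' the run-length filter.
#'
#' @param layout A [GenomeLayout-class].
#' @param profile One element of [generateProfiles()] output.
#' @param config,seed As in [generateReference()].
#' @return A [CoverageTrack-class].
#' @export
simulateSampleCoverage <- function(layout, profile,
                                   config = syntheticConfig(),
                                   seed = 1L) {
  sl <- chromLengths(layout)
  bad <- end(profile$absent) >
    sl[as.character(seqnames(profile$absent))]
  if (any(bad)) stop("absent block outside chromosome")
  withSeed(subSeed(seed, "coverage", profile$sample_id), {
    ws <- config$windowSize
    cov <- RleList(lapply(names(sl), function(chr) {
      len <- sl[[chr]]
      nw <- ceiling(len / ws)
      widths <- rep(ws, nw)
      widths[nw] <- len - ws * (nw - 1L)
      depth <- rpois(nw, profile$mean_depth)
      r <- Rle(depth, widths)
      if (isTRUE(config$noise)) {
        n_ev <- rbinom(1, nw, config$noiseRate)
        if (n_ev > 0) {
          for (k in seq_len(n_ev)) {
            w <- sample(config$noiseWidth[1]:config$noiseWidth[2], 1)
            st <- sample(seq_len(max(1L, len - w)), 1)
            r[st:(st + w - 1L)] <- 0L
          }
        }
      }
      r
    }), compress = FALSE)
    names(cov) <- names(sl)
    for (i in seq_along(profile$absent)) {
      chr <- as.character(seqnames(profile$absent)[i])
      cov[[chr]][start(profile$absent)[i]:end(profile$absent)[i]] <- 0L
    }
    new("CoverageTrack", sampleId = profile$sample_id,
        coverage = cov, seqinfo = seqinfo(layout))
  })
}
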