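## Deterministic seed substreams: every stage and sample draws from a
## seed derived from (master seed, labels), so adding a sample or stage
## never perturbs the draws of the others. Kept below 2^31 - 1.
subSeed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(labels)) h <- (h * 131 + k) %% 1014741823
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

## evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## random DNA of length n as a character string
randomDna <- function(n) {
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE)])
}

## GRanges constructor that carries the full chromosome namespace, so
## later concatenations never merge disjoint seqlevels
grOn <- function(chr, ranges, seqnames, strand = "*") {
  GRanges(factor(chr, levels = seqnames), ranges,
          strand = rep_len(strand, length(ranges)))
}

otherBases <- function(base) setdiff(c("A", "C", "G", "T"), base)
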