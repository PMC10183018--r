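## Variant planting. Coding variants are constructed codon-first: a
## CDS codon and an alternate base are chosen so that the translated
## effect matches the intended class, verified against the standard
## genetic code at construction time, then mapped back to genomic
## coordinates (complementing the alternate base for minus-strand
## genes).

## genomic position of a 1-based spliced-CDS position
genomicPosition <- function(sc, cp) {
  total <- sc$cumw[length(sc$cumw)]
  plus_off <- if (sc$strand == "+") cp else total - cp + 1L
  i <- findInterval(plus_off - 1L, sc$cumw)
  start(sc$pieces)[i] + (plus_off - sc$cumw[i] - 1L)
}

## choose a (cds position, alt base on CDS strand) pair whose effect is
## 'target' ("synonymous"/"nonsynonymous"); NULL after bounded retries.
## usedRaw is a raw vector marking occupied positions on the gene's
## chromosome.
pickCodingChange <- function(sc, target, usedRaw, maxTries = 60L) {
  total <- sc$cumw[length(sc$cumw)]
  n_codons <- total %/% 3L
  code <- GENETIC_CODE
  for (t in seq_len(maxTries)) {
    ci <- sample.int(n_codons, 1) - 1L
    within <- sample.int(3L, 1)
    codon <- as.character(subseq(sc$seq, ci * 3L + 1L, ci * 3L + 3L))
    refb <- substr(codon, within, within)
    for (altb in sample(otherBases(refb))) {
      mut <- codon
      substr(mut, within, within) <- altb
      klass <- if (code[[codon]] == code[[mut]]) "synonymous"
               else "nonsynonymous"
      if (klass != target) next
      cp <- ci * 3L + within
      gpos <- genomicPosition(sc, cp)
      if (usedRaw[gpos] != as.raw(0)) next
      return(list(gpos = gpos, alt_cds = altb, cp = cp))
    }
  }
  NULL
}

#' Simulate genotyped variants with planted selection classes
#'
#' Every gene receives synonymous / non-synonymous SNV counts drawn
#' from its selection class (positive: dN >> dS >= 1; neutral:
#' dN ~ dS; purifying: dS >> dN), each change verified against the
#' genetic code at construction. Non-coding SNVs and indels are
#' scattered over non-CDS, non-gap sequence, plus a set of low-quality
#' artifact SNVs whose site annotations fail the default hard filters.
#' Genotypes: a sample carries a variant with probability
#' `config$carrierRate` when the site lies outside its absent blocks
#' (inside, the call is missing); carried genotypes are heterozygous
#' with the profile's `het_fraction`, else homozygous-alternate.
#'
#' @param reference Output of [generateReference()].
#' @param profiles Output of [generateProfiles()].
#' @param config,seed As in [generateReference()].
#' @return List: `table` (a [VariantTable-class]) and `truth`
#'   (`data.frame` with `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `klass` in synonymous/nonsynonymous/noncoding, `artifact`).
#' @export
simulateVariants <- function(reference, profiles,
                             config = syntheticConfig(), seed = 1L) {
  catalog <- reference$catalog
  seqs <- reference$seqs
  sl <- chromLengths(reference$layout)
  withSeed(subSeed(seed, "variants"), {
    chrom <- character(0); pos <- integer(0)
    refv <- character(0); altv <- character(0)
    gene <- character(0); klass <- character(0)
    artifact <- logical(0)
    used <- lapply(sl, function(len) raw(len))

    ## ---- coding variants per gene
    for (gid in geneIds(catalog)) {
      sc <- splicedCds(catalog, seqs, gid)
      tgt <- drawClassCounts(reference$geneClass[[gid]])
      want <- c(rep("nonsynonymous", tgt[["dN"]]),
                rep("synonymous", tgt[["dS"]]))
      for (w in want) {
        pick <- pickCodingChange(sc, w, used[[sc$chrom]])
        if (is.null(pick)) next   # gene too short for requested count
        used[[sc$chrom]][pick$gpos] <- as.raw(1)
        g_ref <- as.character(subseq(seqs[[sc$chrom]], pick$gpos,
                                     pick$gpos))
        g_alt <- if (sc$strand == "+") pick$alt_cds
                 else chartr("ACGT", "TGCA", pick$alt_cds)
        chrom <- c(chrom, sc$chrom); pos <- c(pos, pick$gpos)
        refv <- c(refv, g_ref); altv <- c(altv, g_alt)
        gene <- c(gene, gid); klass <- c(klass, w)
        artifact <- c(artifact, FALSE)
      }
    }

    ## ---- mask of positions closed to non-coding variants:
    ## gaps, CDS (padded by 1) and already-used positions
    closed <- reduce(c(granges(assemblyGaps(reference$layout)),
                       unlist(cdsRanges(catalog), use.names = FALSE)),
                     ignore.strand = TRUE)
    occ <- used
    for (i in seq_along(closed)) {
      chr <- as.character(seqnames(closed)[i])
      a <- max(1L, start(closed)[i] - 1L)
      b <- min(sl[[chr]], end(closed)[i] + 1L)
      occ[[chr]][a:b] <- as.raw(1)
    }
    bases <- c("A", "C", "G", "T")
    altmat <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                    c("A", "C", "T"), c("A", "C", "G"))

    ## draw 'need' open positions such that p .. p+w is unoccupied;
    ## marks them occupied and returns (chr, p)
    draw_open <- function(need, w = 0L) {
      out_chr <- character(0); out_p <- integer(0)
      while (length(out_p) < need) {
        m <- 2L * (need - length(out_p)) + 16L
        chr <- sample(names(sl), m, replace = TRUE,
                      prob = as.numeric(sl))
        p <- as.integer(floor(runif(m) * (sl[chr] - w - 1))) + 1L
        valid <- !duplicated(paste(chr, p))
        for (cn in names(sl)) {
          idx <- which(chr == cn & valid)
          if (!length(idx)) next
          hit <- rep(FALSE, length(idx))
          for (k in 0:w)
            hit <- hit | occ[[cn]][p[idx] + k] != as.raw(0)
          valid[idx[hit]] <- FALSE
        }
        chr <- chr[valid]; p <- p[valid]
        take <- seq_len(min(length(p), need - length(out_p)))
        chr <- chr[take]; p <- p[take]
        for (cn in unique(chr))
          occ[[cn]][p[chr == cn]] <<- as.raw(1)
        out_chr <- c(out_chr, chr); out_p <- c(out_p, p)
      }
      list(chr = out_chr, p = out_p)
    }
    base_at <- function(chr, p, w = 0L) {
      w <- rep_len(w, length(p))
      out <- character(length(p))
      for (cn in unique(chr)) {
        idx <- chr == cn
        out[idx] <- as.character(Biostrings::extractAt(
          seqs[[cn]], IRanges(p[idx], width = w[idx] + 1L)))
      }
      out
    }

    ## ---- non-coding SNVs (plus artifacts failing hard filters)
    n_nc <- config$nNoncodingSnvs + config$nArtifacts
    dp <- draw_open(n_nc)
    b <- base_at(dp$chr, dp$p)
    a <- altmat[cbind(match(b, bases), sample.int(3L, n_nc, TRUE))]
    chrom <- c(chrom, dp$chr); pos <- c(pos, dp$p)
    refv <- c(refv, b); altv <- c(altv, a)
    gene <- c(gene, rep(NA_character_, n_nc))
    klass <- c(klass, rep("noncoding", n_nc))
    artifact <- c(artifact, seq_len(n_nc) > config$nNoncodingSnvs)

    ## ---- non-coding indels
    n_ind <- config$nIndels
    iw <- sample(1:5, n_ind, replace = TRUE)
    del <- runif(n_ind) < 0.5
    i_chr <- character(n_ind); i_p <- integer(n_ind)
    for (w in 1:5) {
      idx <- which(iw == w)
      if (!length(idx)) next
      dp <- draw_open(length(idx), w + 1L)
      i_chr[idx] <- dp$chr; i_p[idx] <- dp$p
    }
    anchor <- base_at(i_chr, i_p)
    r <- ifelse(del, base_at(i_chr, i_p, iw), anchor)
    a <- ifelse(del, anchor,
                paste0(anchor, vapply(iw, randomDna, "")))
    chrom <- c(chrom, i_chr); pos <- c(pos, i_p)
    refv <- c(refv, r); altv <- c(altv, a)
    gene <- c(gene, rep(NA_character_, n_ind))
    klass <- c(klass, rep("noncoding", n_ind))
    artifact <- c(artifact, rep(FALSE, n_ind))

    n <- length(pos)
    ## ---- site annotations: artifacts fail QD or FS
    qd <- runif(n, 15, 35); fs <- runif(n, 0, 8)
    mq <- runif(n, 50, 60)
    mqrs <- runif(n, -2, 2); rprs <- runif(n, -2, 2)
    art <- which(artifact)
    half <- art[seq_len(length(art) %/% 2)]
    qd[half] <- runif(length(half), 0.1, 1.9)
    fs[setdiff(art, half)] <- runif(length(setdiff(art, half)), 65, 120)
    info <- data.frame(QD = qd, FS = fs, MQ = mq, MQRankSum = mqrs,
                       ReadPosRankSum = rprs)

    ## ---- genotypes
    var_gr <- GRanges(chrom, IRanges(pos, width = 1L))
    gmat <- matrix(NA_integer_, n, length(profiles),
                   dimnames = list(NULL, names(profiles)))
    eligible <- matrix(TRUE, n, length(profiles))
    for (s in seq_along(profiles)) {
      blocked <- !is.na(findOverlaps(var_gr, profiles[[s]]$absent,
                                     select = "first",
                                     ignore.strand = TRUE))
      eligible[, s] <- !blocked
    }
    for (s in seq_along(profiles)) {
      hf <- profiles[[s]]$het_fraction
      carrier <- runif(n) < config$carrierRate
      copies <- ifelse(runif(n) < hf, 1L, 2L)
      g <- ifelse(carrier, copies, 0L)
      g[!eligible[, s]] <- NA_integer_
      gmat[, s] <- g
    }
    ## every variant needs at least one carrier among eligible samples
    carried <- rowSums(!is.na(gmat) & gmat >= 1L) > 0L
    fix <- which(!carried & rowSums(eligible) > 0L)
    for (i in fix) {
      el <- which(eligible[i, ])
      s <- el[sample.int(length(el), 1)]
      hf <- profiles[[s]]$het_fraction
      gmat[i, s] <- if (runif(1) < hf) 1L else 2L
    }

    ord <- order(match(chrom, names(sl)), pos, altv)
    rec <- data.frame(chrom = chrom[ord], pos = pos[ord],
                      ref = refv[ord], alt = altv[ord],
                      type = classifyVariant(refv[ord], altv[ord]),
                      stringsAsFactors = FALSE)
    table <- new("VariantTable", records = rec,
                 info = info[ord, , drop = FALSE],
                 genotypes = gmat[ord, , drop = FALSE])
    truth <- data.frame(chrom = chrom[ord], pos = pos[ord],
                        ref = refv[ord], alt = altv[ord],
                        gene_id = gene[ord], klass = klass[ord],
                        artifact = artifact[ord],
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(table = table, truth = truth)
  })
}
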