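#' Read a VCF into a VariantTable
#'
#' Multi-allelic sites are decomposed into one record per alternate
#' allele; a sample's genotype for a record is the number of copies of
#' that record's alternate allele (0, 1, 2; NA when the call is
#' missing). Phased (`|`) and unphased (`/`) separators are both
#' accepted. Records whose REF or ALT contain symbolic or non-ACGT
#' alleles are skipped with a warning. Haploid genotype calls are
#' counted as homozygous by convention (two copies), with a message.
#'
#' @param path Path to a VCF 4.x file with a GT FORMAT field.
#' @return A [VariantTable-class].
#' @export
readVariants <- function(path) {
  vcf <- readVcf(path, genome = "unknown")
  if (!"GT" %in% rownames(geno(header(vcf))))
    stop("VCF has no GT field in FORMAT")
  rr <- rowRanges(vcf)
  refs <- as.character(ref(vcf))
  alts <- alt(vcf)
  gt <- geno(vcf)$GT
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1)
  samples <- colnames(gt)
  inf <- info(vcf)

  info_cols <- names(inf)[vapply(inf, function(col)
    is.numeric(col) || is(col, "NumericList") || is(col, "IntegerList"),
    NA)]

  nalt <- S4Vectors::elementNROWS(alts)
  site <- rep(seq_along(rr), nalt)          # source site per record
  aidx <- sequence(nalt)                    # alt index per record
  chrom <- as.character(seqnames(rr))[site]
  pos <- start(rr)[site]
  refv <- refs[site]
  altv <- as.character(unlist(alts))

  ok <- grepl("^[ACGT]+$", refv) & grepl("^[ACGT]+$", altv)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(n_skipped, " record(s) with symbolic or non-ACGT alleles skipped")

  ## allele lists per site x sample, split once
  spl <- strsplit(gt, "[/|]")
  dim(spl) <- dim(gt)
  ploidy1 <- matrix(lengths(spl) == 1L, nrow(gt))
  if (any(ploidy1))
    message("haploid genotype(s) encountered; counted as homozygous")
  gmat <- matrix(NA_integer_, length(site), length(samples))
  for (s in seq_along(samples)) {
    col <- spl[, s]
    missing_call <- vapply(col, function(al)
      !length(al) || any(al == "."), NA)[site]
    k <- mapply(function(i, a) sum(spl[[i, s]] == as.character(a)),
                site, aidx)
    hap <- ploidy1[site, s]
    k[hap] <- 2L * k[hap]
    k[missing_call] <- NA_integer_
    gmat[, s] <- as.integer(k)
  }

  imat <- list()
  for (cn in info_cols) {
    v <- inf[[cn]]
    if (is.numeric(v)) {
      imat[[cn]] <- as.numeric(v)[site]
    } else {
      imat[[cn]] <- mapply(function(i, a) {
        el <- v[[i]]
        if (length(el) >= a) as.numeric(el[a])
        else if (length(el)) as.numeric(el[1]) else NA_real_
      }, site, aidx)
    }
  }

  chrom <- chrom[ok]; pos <- pos[ok]; refv <- refv[ok]; altv <- altv[ok]
  gmat <- gmat[ok, , drop = FALSE]
  imat <- lapply(imat, function(v) v[ok])

  colnames(gmat) <- samples
  rownames(gmat) <- NULL
  rec <- data.frame(chrom = chrom, pos = pos, ref = refv, alt = altv,
                    stringsAsFactors = FALSE)
  keep <- !duplicated(paste(rec$chrom, rec$pos, rec$ref, rec$alt))
  rec <- rec[keep, , drop = FALSE]
  gmat <- gmat[keep, , drop = FALSE]
  if (length(imat)) {
    infd <- as.data.frame(lapply(imat, function(v) v[keep]),
                          optional = TRUE)
  } else {
    infd <- as.data.frame(matrix(nrow = nrow(rec), ncol = 0))
  }
  rec$type <- classifyVariant(rec$ref, rec$alt)
  rownames(rec) <- NULL
  rownames(infd) <- NULL
  new("VariantTable", records = rec, info = infd, genotypes = gmat)
}

#' Classify decomposed alleles as SNV / insertion / deletion / other
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector in `c("SNV","insertion","deletion","other")`.
#' @examples
#' classifyVariant(c("A", "AT", "A"), c("G", "A", "AT"))
#' @export
classifyVariant <- function(ref, alt) {
  out <- rep("other", length(ref))
  out[nchar(ref) == 1L & nchar(alt) == 1L] <- "SNV"
  ins <- nchar(alt) > nchar(ref) &
    substr(alt, 1L, nchar(ref)) == ref
  del <- nchar(ref) > nchar(alt) &
    substr(ref, 1L, nchar(alt)) == alt
  out[ins] <- "insertion"
  out[del] <- "deletion"
  out
}

#' @rdname VariantTable-class
#' @export
setMethod("variantRecords", "VariantTable", function(x) x@records)

#' @rdname VariantTable-class
#' @export
setMethod("siteInfo", "VariantTable", function(x) x@info)

#' @rdname VariantTable-class
#' @export
setMethod("genotypeCopies", "VariantTable", function(x) x@genotypes)

#' Sample names of a VariantTable
#' @param x A [VariantTable-class].
#' @return Character vector.
#' @export
variantSamples <- function(x) colnames(x@genotypes)

setMethod("show", "VariantTable", function(object) {
  tab <- table(factor(object@records$type,
                      c("SNV", "insertion", "deletion", "other")))
  cat("VariantTable:", nrow(object@records), "record(s) across",
      ncol(object@genotypes), "sample(s) (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

#' Hard-filter configuration
#'
#' One row per rule: a record of the matching type is *removed* when
#' the named annotation is present and satisfies
#' `annotation <comparator> threshold`. Records lacking the annotation
#' are never failed by that rule (the GATK VariantFiltration
#' convention). Rule type `"indel"` covers insertions and deletions.
#'
#' @param type,annotation,comparator,threshold Vectors defining rules;
#'   comparators must be one of `<`, `>`, `<=`, `>=`.
#' @return A `data.frame` usable by [hardFilter()].
#' @export
filterConfig <- function(type, annotation, comparator, threshold) {
  cfg <- data.frame(type = type, annotation = annotation,
                    comparator = comparator, threshold = threshold,
                    stringsAsFactors = FALSE)
  bad <- setdiff(cfg$comparator, c("<", ">", "<=", ">="))
  if (length(bad))
    stop("config error: unknown comparator(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(cfg$threshold)))
    stop("config error: thresholds must be finite")
  cfg
}

#' Generic GATK-style hard-filter defaults
#'
#' SNVs fail on QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
#' ReadPosRankSum < -8; indels on QD < 2, FS > 200,
#' ReadPosRankSum < -20. Fully user-overridable.
#'
#' @return A filter configuration `data.frame`.
#' @export
defaultFilterConfig <- function() {
  filterConfig(
    type = c("SNV", "SNV", "SNV", "SNV", "SNV",
             "indel", "indel", "indel"),
    annotation = c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum",
                   "QD", "FS", "ReadPosRankSum"),
    comparator = c("<", ">", "<", "<", "<", "<", ">", "<"),
    threshold = c(2, 60, 40, -12.5, -8, 2, 200, -20))
}

#' Apply hard filters to a VariantTable
#'
#' @param x A [VariantTable-class].
#' @param config A rule table from [filterConfig()];
#'   [defaultFilterConfig()] by default.
#' @return The filtered [VariantTable-class]. Idempotent.
#' @export
hardFilter <- function(x, config = defaultFilterConfig()) {
  stopifnot(is(x, "VariantTable"))
  bad <- setdiff(config$comparator, c("<", ">", "<=", ">="))
  if (length(bad))
    stop("config error: unknown comparator(s): ", paste(bad, collapse = ", "))
  if (!nrow(x@records) || !nrow(config)) return(x)
  fails <- rep(FALSE, nrow(x@records))
  rtype <- ifelse(x@records$type %in% c("insertion", "deletion"),
                  "indel", x@records$type)
  for (i in seq_len(nrow(config))) {
    ann <- config$annotation[i]
    if (!ann %in% names(x@info)) next
    v <- x@info[[ann]]
    hit <- switch(config$comparator[i],
      "<"  = v <  config$threshold[i],
      ">"  = v >  config$threshold[i],
      "<=" = v <= config$threshold[i],
      ">=" = v >= config$threshold[i])
    hit[is.na(hit)] <- FALSE           # missing annotation passes
    fails <- fails | (hit & rtype == config$type[i])
  }
  keep <- !fails
  new("VariantTable",
      records = x@records[keep, , drop = FALSE],
      info = x@info[keep, , drop = FALSE],
      genotypes = x@genotypes[keep, , drop = FALSE])
}

#' Zygosity partition for one sample
#'
#' Counts heterozygous (one copy of the alternate allele) and
#' homozygous-alternate (two copies) genotype calls per variant type.
#' Reference-homozygous and missing calls contribute nothing.
#'
#' @param x A [VariantTable-class].
#' @param sample Sample name.
#' @return `data.frame` with columns `sample_id`, `type` (`SNV`,
#'   `indel`), `n_het`, `n_hom_alt`.
#' @export
zygosityPartition <- function(x, sample) {
  stopifnot(is(x, "VariantTable"))
  if (!sample %in% variantSamples(x))
    stop("unknown sample: ", sample)
  copies <- x@genotypes[, sample]
  rtype <- ifelse(x@records$type %in% c("insertion", "deletion"),
                  "indel", x@records$type)
  out <- lapply(c("SNV", "indel"), function(tp) {
    sel <- rtype == tp & !is.na(copies)
    data.frame(sample_id = sample, type = tp,
               n_het = sum(copies[sel] == 1L),
               n_hom_alt = sum(copies[sel] == 2L))
  })
  do.call(rbind, out)
}

#' Variant density per kilobase for one sample
#'
#' Number of the sample's non-reference records of each type divided by
#' the assembly length in kb.
#'
#' @param x A (typically hard-filtered) [VariantTable-class].
#' @param sample Sample name.
#' @param layout A [GenomeLayout-class] supplying the denominator.
#' @param excludeGaps If `TRUE`, use the non-gap assembly length.
#' @return `data.frame` with `sample_id`, `snv_per_kb`, `indel_per_kb`,
#'   `genome_length`.
#' @export
variantDensity <- function(x, sample, layout, excludeGaps = FALSE) {
  stopifnot(is(x, "VariantTable"), is(layout, "GenomeLayout"))
  gl <- genomeLength(layout, excludeGaps = excludeGaps)
  if (gl <= 0) stop("zero-length genome")
  copies <- x@genotypes[, sample]
  carried <- !is.na(copies) & copies >= 1L
  n_snv <- sum(carried & x@records$type == "SNV")
  n_indel <- sum(carried & x@records$type %in% c("insertion", "deletion"))
  data.frame(sample_id = sample,
             snv_per_kb = n_snv / (gl / 1000),
             indel_per_kb = n_indel / (gl / 1000),
             genome_length = gl)
}

#' Per-sample density and zygosity summary tables
#'
#' @param x A [VariantTable-class].
#' @param layout A [GenomeLayout-class].
#' @return A list with elements `density` (one row per sample, densities
#'   to be written at 4 decimals) and `zygosity` (counts and percentages
#'   of non-reference calls per sample and type).
#' @export
variantSummary <- function(x, layout) {
  samples <- variantSamples(x)
  dens <- do.call(rbind, lapply(samples, variantDensity,
                                x = x, layout = layout))
  zyg <- do.call(rbind, lapply(samples, zygosityPartition, x = x))
  tot <- zyg$n_het + zyg$n_hom_alt
  zyg$pct_het <- ifelse(tot > 0, 100 * zyg$n_het / tot, NA_real_)
  zyg$pct_hom <- ifelse(tot > 0, 100 * zyg$n_hom_alt / tot, NA_real_)
  list(density = dens, zygosity = zyg)
}
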