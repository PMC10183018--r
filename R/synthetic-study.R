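#' Write a VariantTable as a VCF 4.2 file
#'
#' Emits the numeric site annotations as INFO fields and per-sample GT
#' calls (`0/0`, `0/1`, `1/1`, `./.`). The result reads back through
#' [readVariants()] unchanged.
#'
#' @param x A [VariantTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVcfFile <- function(x, path) {
  rec <- variantRecords(x)
  inf <- siteInfo(x)
  gm <- genotypeCopies(x)
  hdr <- c("##fileformat=VCFv4.2",
           vapply(names(inf), function(cn) sprintf(
             "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
             cn, cn), ""),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                   "FILTER", "INFO", "FORMAT", colnames(gm)),
                 collapse = "\t"))
  info_str <- if (ncol(inf)) {
    apply(inf, 1, function(row)
      paste(sprintf("%s=%.4f", names(inf), row), collapse = ";"))
  } else rep(".", nrow(rec))
  gt_code <- function(copies) {
    out <- rep("./.", length(copies))
    out[!is.na(copies) & copies == 0L] <- "0/0"
    out[!is.na(copies) & copies == 1L] <- "0/1"
    out[!is.na(copies) & copies == 2L] <- "1/1"
    out
  }
  gts <- apply(gm, 2, gt_code)
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = nrow(rec))
  body <- if (nrow(rec)) {
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, "50", "PASS",
          info_str, "GT",
          apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a complete synthetic study
#'
#' Runs the generator end to end: reference bundle, per-sample
#' profiles, coverage tracks and genotyped variants. With `dir` set,
#' also writes every file a real-data run would consume — reference
#' FASTA, gene GFF3, gaps BED, chrom.sizes, one bedGraph per sample,
#' one joint VCF, gene-set and term TSVs — plus truth TSVs and BEDs.
#'
#' @param config,seed As in [generateReference()].
#' @param dir Optional output directory (created if needed).
#' @return List: `reference`, `profiles`, `tracks` (named list of
#'   [CoverageTrack-class]), `variants` (as [simulateVariants()]),
#'   `files` (named paths when `dir` given).
#' @export
generateStudy <- function(config = syntheticConfig(), seed = 1L,
                          dir = NULL) {
  reference <- generateReference(config, seed)
  profiles <- generateProfiles(reference, config, seed)
  tracks <- lapply(profiles, function(p)
    simulateSampleCoverage(reference$layout, p, config, seed))
  variants <- simulateVariants(reference, profiles, config, seed)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(dir, paste0(...))
    files <- list(fasta = fp("reference.fa"), gff3 = fp("genes.gff3"),
                  gaps = fp("gaps.bed"), sizes = fp("chrom.sizes"),
                  vcf = fp("variants.vcf"),
                  gene_sets = fp("gene_sets.tsv"),
                  term_map = fp("term_map.tsv"),
                  truth_variants = fp("truth_variants.tsv"),
                  truth_classes = fp("truth_gene_classes.tsv"))
    writeXStringSet(reference$seqs, files$fasta)
    writeGff3Genes(reference$catalog, files$gff3)
    writeBed(assemblyGaps(reference$layout), files$gaps)
    write.table(data.frame(names(chromLengths(reference$layout)),
                           chromLengths(reference$layout)),
                files$sizes, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeVcfFile(variants$table, files$vcf)
    sets <- reference$geneSets
    write.table(data.frame(
      gene_id = unlist(sets, use.names = FALSE),
      set_name = rep(names(sets), lengths(sets))),
      files$gene_sets, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    tm <- reference$termMap
    write.table(data.frame(
      gene_id = unlist(tm, use.names = FALSE),
      term_id = rep(names(tm), lengths(tm))),
      files$term_map, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    write.table(variants$truth, files$truth_variants, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(reference$geneClass),
                           omega_class = unname(reference$geneClass)),
                files$truth_classes, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (sid in names(tracks)) {
      files[[paste0("bedgraph_", sid)]] <- fp(sid, ".bedGraph")
      writeBedGraph(tracks[[sid]], files[[paste0("bedgraph_", sid)]])
      files[[paste0("zcr_truth_", sid)]] <- fp(sid, ".zcr_truth.bed")
      writeBed(profiles[[sid]]$zcr_truth,
               files[[paste0("zcr_truth_", sid)]])
    }
  }
  list(reference = reference, profiles = profiles, tracks = tracks,
       variants = variants, files = files)
}
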