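---
title: "Detecting presence/absence variation and selection from multi-sample coverage: methods and design"
author: "zcrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zcrtools methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

## Zero-coverage regions

A zero-coverage region (ZCR) for a sample is a maximal run of reference
positions with read depth exactly zero over *non-gap* sequence, of
length at least `minLength` (default 2000 bp, boundary inclusive: a
2000-bp run qualifies). Assembly gaps — runs of N in the reference —
must be masked because no read can map inside them, so an unmasked gap
would masquerade as biological signal.

ZCRs are a deliberately specific, insensitive detector: they flag loci
that are either homozygously deleted from the sequenced genome or so
divergent from the reference that no reads align. Coverage alone cannot
distinguish these two causes, and the package does not try.
Heterozygous deletions (depth halved, not zeroed) and regions of merely
low coverage are outside the statistic's reach by construction.

Two behaviours are possible where a zero run abuts an assembly gap. The
default is **non-bridging**: a gap terminates the run, so a ZCR is
never called across a gap — the conservative choice, since the
reference provides no evidence inside the gap. With
`bridgeGaps = TRUE`, a zero run interrupted by gaps qualifies on its
total *non-gap* zero length and is reported as its non-gap pieces
(which may individually be shorter than `minLength`). Both are exposed
because the upstream convention (masking gaps out of a coverage track
before run extraction) is ambiguous between them.

The genome ZCR percentage divides total ZCR bases by the full assembly
length by default; a non-gap denominator is available
(`denominator = "nongap"`), since pre-masked tracks make either reading
defensible.

## Gene overlap and gene-set summaries

A gene is ZCR-flagged when at least one base of at least one exon of
its **canonical transcript** intersects a ZCR (half-open/closed
conventions cancel out in GRanges arithmetic; intron-only overlap never
flags). Canonical-transcript exons are the default because the same
transcript carries the dN/dS evaluation; `useExons = "gene_span"`
intersects whole gene spans for an annotation-agnostic variant. The
canonical transcript is the one tagged `canonical`/`Ensembl_canonical`
in the GFF3 when present, else the longest total CDS, ties broken by
smallest transcript identifier — a deterministic stand-in for an
external annotator's notion of "canonical" that synthetic genomes lack.

Per-sample flags OR together into a combined ("Comb.") column, and
per-set percentages are reported to one decimal. The combined
percentage can never fall below a per-sample percentage (union
monotonicity), which the tests assert.

## Variant metrics

VCF records are decomposed per alternate allele on read; downstream
counting deduplicates by (chrom, pos, ref, alt). A sample's genotype
for a record is the number of copies of that record's alternate allele
(0/1/2, NA for missing); haploid calls are counted as homozygous by
convention, with a message. Hard filtering follows the GATK
VariantFiltration convention: a record is removed when any configured
rule for its type fires, and a record *missing* an annotation is never
failed by that rule. The default thresholds are the generic GATK
recommendations (SNV: QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5,
ReadPosRankSum < −8; indel: QD < 2, FS > 200, ReadPosRankSum < −20)
and are fully user-overridable, since study-specific thresholds are
typically tuned per cohort. Densities divide a sample's carried
records per type by the assembly length in kb (gaps included by
default, configurable — the conventional "per genome" denominator).

## Composite dN/dS

For each coding SNV the spliced CDS of the canonical transcript is
assembled (reverse-complemented for minus-strand genes), the affected
codon is located, the alternate base substituted (complemented on the
minus strand), and both codons translated with the standard genetic
code. Identical amino acids — including stop-to-stop — are synonymous;
anything else, including stop gain and stop loss, is non-synonymous.
Indels, UTR and intergenic changes are excluded. Per gene, dN and dS
count *distinct* alternate alleles carried by at least one sample:
pooling across samples without multiplicity, because an allele shared
by all individuals is one mutation, not three (per-sample-occurrence
weighting is available as `countPerSample = TRUE`; it would scale dN
and dS nearly equally anyway).

The ratio dN/dS is defined only for genes with dS > 0; genes with
dN > 0, dS = 0 stay in the census but get no ratio and are *not*
called positive (an optional add-one pseudocount mode defines a ratio
for them, off by default). Positive selection is called at ratio
strictly > 1; a "high" set uses ratio ≥ 10, boundary inclusive. The
Manhattan table reports log10(dN/dS) per gene at the gene midpoint, so
neutrality sits at 0; genes with dN = 0 are excluded there because the
logarithm is undefined. This composite ratio is a descriptive count
statistic — there is no site/branch model, no codon-frequency
normalisation and no significance test per gene; treat the > 1 set as
an enrichment substrate, not as per-gene inference.

For real data annotated externally, `readConsequenceTable()` ingests a
per-allele consequence TSV and maps terms through an explicit editable
table (`missense_variant`, `stop_gained`, `stop_lost`, `start_lost` →
non-synonymous; `synonymous_variant`, `stop_retained_variant` →
synonymous); unmapped terms are ignored rather than guessed.

## Enrichment and set comparison

Over-representation uses the one-sided hypergeometric upper tail
P(X ≥ k) per term (k = query∩term, n = query, K = term, N = universe),
with Benjamini–Hochberg adjustment across tested terms; terms with no
query overlap are omitted. The universe defaults to every gene in the
annotation — the most transparent choice when the exact annotated
subset used by other tools is unknown; callers can pass any universe.
Set partitions (shared / A-only / B-only with percentages of the
union) compare, e.g., the combined ZCR gene list with the
positive-selection list.

## Presence/absence haplotype patterns

For user-named loci (typically gene spans or sub-locus intervals), the
absence fraction is the proportion of locus bases covered by a
sample's ZCRs; a locus is called absent at fraction ≥ 0.5, boundary
inclusive. The 0.5 rule is this package's operationalisation of a
judgment usually made by eye on coverage plots; it is a parameter, not
a claim. Discordant loci have mixed calls across samples. Complementary
pairs are two loci whose absence vectors are exact complements with
neither vector constant — constant vectors are excluded because a locus
absent (or present) in everybody carries no between-sample signal. This
is the signature of two alternative haplotypes assembled in tandem in
the reference, each individual carrying one.

# The synthetic study

The generator's defaults encode the study design the package targets:

* three chromosomes (2 Mb, 1 Mb, 0.5 Mb) — large enough for 2-kb run
  statistics, small enough for the full pipeline in seconds;
* 200 genes: a compact MHC-like locus of two adjacent 7-gene sub-loci,
  an NLR-like cluster of 50 genes filling the distal 40% of the
  smallest chromosome, and background genes elsewhere; CDS lengths
  300–750 bp in 1–3 pieces, always divisible by 3;
* twelve assembly gaps (1–5 kb), written as N runs in the FASTA and as
  a BED, kept clear of the clusters;
* three samples mirroring a clonal/outbred contrast: two clonal
  samples (mean depth 55×, heterozygous genotype fraction 0.03) and
  one outbred sample (50×, 0.6). Depth 50–60× and the ~3% vs ~56–60%
  zygosity split are the regimes such studies report;
* per-sample absent blocks: the complementary MHC pattern (sub-locus A
  absent in the outbred sample, B absent in both clonal samples),
  three large blocks (20–50 kb) inside the NLR-like cluster per
  sample, six background blocks (3–10 kb), and two sub-threshold
  blocks (< 2 kb) that must *not* be reported;
* coverage as piecewise-constant 500-bp windows drawn Poisson around
  the profile depth — per-read simulation would add nothing to what
  the ZCR statistic can see — plus an optional short-noise process
  (zero runs of 500–1500 bp at rate 1e-3 per window) to exercise the
  length filter;
* variants: per-gene (dN, dS) targets drawn by selection class
  (positive: dS ≥ 1, dN ≫ dS; neutral: dN ~ Poisson(dS); purifying:
  dS ≫ dN), each planted change chosen codon-first and verified
  against the genetic code at construction; 8000 non-coding SNVs, 2000
  indels, and 600 artifact SNVs whose QD or FS values fail the default
  hard filters; carriers drawn at rate 0.85 among samples whose absent
  blocks do not cover the site (inside a block the call is missing);
  30 positive, 85 neutral and 85 purifying genes, two thirds of the
  positive class inside the NLR-like cluster.

Seeding is hierarchical: every stage and sample derives its own
substream from (master seed, stage, sample), so adding a sample never
perturbs the others and everything is reproducible byte-for-byte.

What the generator does **not** emulate: read-level error, mappability
structure, GC bias, heterozygous deletions, and divergence as anything
other than an absent block (divergence and deletion are
indistinguishable to a coverage-only statistic, so simulating them
separately would be untestable). Passing tests therefore demonstrate
algorithmic correctness on idealised coverage and genotype structure,
not robustness to alignment artefacts in real data.

# Numerical and design choices

* **Coordinates.** Internally everything is a `GRanges` (1-based,
  closed), the native convention of the R/Bioconductor stack; BED and
  bedGraph convert at the I/O boundary, GFF3 is native. One convention
  everywhere removes the off-by-one class of bugs.
* **Boundaries.** "≥ 2 kb" is inclusive; absence calls at fraction
  exactly 0.5 are absent; positive selection is strict at 1 and
  inclusive at 10.
* **Degenerate inputs.** Empty gene sets, empty universes, zero-length
  loci, non-positive `minLength`, overlapping bedGraph intervals and
  unsorted BED input are errors, not silent corrections. Missing INFO
  annotations pass hard filters. Symbolic VCF alleles are skipped with
  a warning.
* **Ties.** Canonical-transcript ties break lexicographically;
  enrichment output sorts by (q, p).
* **Problem sizes in the test suite.** The oracle-equivalence tests
  run ~100 random 5–20 kb tracks against a literal per-base scan; the
  consequence classifier is checked exhaustively over all 576
  single-base codon substitutions on both strands against an
  independent translation oracle; recovery tests run at the default
  study scale (3.5 Mb, 200 genes, ~12,000 variants), which keeps the
  whole suite in the minutes range on one CPU.

# Limitations

ZCRs undercount structural variation: heterozygous deletions,
low-coverage divergence and anything shorter than the length threshold
are invisible. The composite dN/dS is a count ratio with no
evolutionary model and is undefined for genes without synonymous
variants — genome-scale conclusions should rest on the enrichment
statistics, not individual gene ratios. The enrichment module performs
flat term testing only: no ontology-graph propagation and no semantic
summarisation of redundant terms.
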