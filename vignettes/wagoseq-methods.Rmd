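---
title: "Methods: classifying Argonaute-bound small RNAs and calling their targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying Argonaute-bound small RNAs and calling their targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Nematode germlines express several Argonaute proteins, each loaded with a
distinct class of small RNAs: miRNAs, 26G primary siRNAs, and the highly
abundant 22G secondary siRNAs made by RdRPs. Immunoprecipitating one
Argonaute and sequencing its bound 18-30 nt RNAs asks two questions: *what
kind of small RNA does this Argonaute carry* (length mode, 5' nucleotide,
annotation class), and *what does it target* (repeat loci versus mature
mRNAs), including how targeting changes across developmental stages
(target plasticity, e.g. an NRDE-3-class Argonaute moving from repeats to
mRNAs during spermatogenesis).

`wagoseq` implements that analysis as a reusable pipeline: exact placement
of reads on genome and spliced transcriptome, a nine-category read
classifier, a coverage-enrichment caller for WAGO-targeted repeat loci
("WAGO-repeats"), an rpkm-threshold caller for antisense mRNA targets, and
comparative summaries (size/first-nucleotide profiles, metagene 5'-bias
curves, Z-score matrices, PCA, Venn overlaps, plasticity series). A
first-class synthetic-data module generates a genome, annotations and
archetype-specific IP libraries with ground truth, so the whole pipeline
is testable end to end.

## Coordinate conventions and containers

Internally every interval is a `GenomicRanges::GRanges` (1-based, closed),
the standard container of the R genomics ecosystem; BED (0-based
half-open) and GFF3 (1-based closed) are converted at the IO boundary.
Round-trips through `read_bed()`/`write_bed()` are bit-exact, and a GFF3
exon `(s, e)` always has width `e - s + 1`. Reads are stored as DNA;
first-nucleotide reporting maps T to U to match the A/C/G/U convention of
small RNA figures. Reads containing N are dropped at load time (exact
placement cannot use them) and tallied.

## Read placement

Placement is exact full-length matching on both genome strands and
against spliced transcript sequences (so antisense reads spanning
exon-exon junctions are found; they have transcript hits but no genome
hit and are *not* "no match"). Matching uses Aho-Corasick multi-pattern
search (Biostrings `PDict` with a trusted band over the shortest read)
against subjects that concatenate every contig and its reverse complement
with `N` spacers, which a valid read can never match across. Exactness
(no mismatches) is a deliberate default: it is verifiable against a
brute-force substring scan, which the test suite does for 1,000 random
reads on a small two-contig genome with duplicated segments.

Coverage tracks are strand-combined. A read with `n` genome hits
contributes `count / n` to every base of each hit (fractional multimapper
weighting conserves total mass), and the track is scaled by
`N0 / total mapped reads`. The normalization target `N0` defaults to 30
million reads; with ~22 nt reads on a 280 Mb genome that is ~2.4x mean
coverage (reported as ~2.5x). Synthetic runs scale `N0` to 200,000 on the
2 Mb genome (~2.2x mean), preserving the meaning of every fold threshold.

## The nine-category classifier

Each read receives exactly one label by a strict priority cascade in the
order: rRNA, tRNA, miRNA, WAGO-repeats, antisense mRNA, intron,
intergenic, no match, sense mRNA. Design choices:

* Interval classes fire when a genome hit overlaps a class interval by at
  least 50% of the read length (`min_overlap_frac`, configurable). The
  50% rule is robust to 1-2 bp boundary noise.
* Sense/antisense mRNA require a full-length exact transcript hit.
* "No match" applies only when a read has neither genome nor transcript
  hits; "intergenic" is the fallback for genome-mapped reads for which no
  other label fires. Because the sense-mRNA condition is checked before
  that fallback, the cascade is a true partition; this resolves the
  ambiguity of where the sense class sits relative to intergenic.
* Multimapping reads take the best (highest-priority) label over all
  their hits, so adding an annotation class can never demote a read
  (priority monotonicity, property-tested).

## WAGO-repeat locus calling

The caller is the published procedure with every threshold exposed in
`caller_params()`:

1. normalize each WAGO-class library's coverage to `N0` (default 30 M);
2. seed windows = maximal runs of bases with coverage >= `seed_fold`
   (default 20) times that library's mean genome coverage (mitochondrial
   contigs excluded from the mean) — 20 x ~2.5 is the 50x absolute
   cutoff; seeds are pooled over all libraries;
3. merge pooled seeds within `merge_dist` (default 2,000 bp), with
   bedtools `mergeBed -d` gap semantics (gap <= D merges; transitive
   closure; never across contigs); `merge_within()` is a simple sorted
   sweep, verified in tests against an independent boolean-matrix
   transitive-closure oracle and against `IRanges::reduce`;
4. drop merged loci shorter than `min_length` (default 50 bp);
5. keep loci with fold enrichment (locus mean coverage / genome mean)
   >= `enrich_fold` (default 10) in at least one library. The enrichment
   baseline is the genome mean of the same library — the reading
   supported by the phrase "relative to mean coverage"; whether the
   original analysis instead used the initial locus set as background is
   not fully explicit, so the baseline is a documented choice;
6. remove loci overlapping rRNA, tRNA or miRNA annotation by >= 1 bp or
   lying on a mitochondrial contig (strictest reading of "remove loci
   related to"); removed loci are kept in a `blacklisted` attribute.

Per-library locus rpkm (weighted overlapping reads / locus kb / mapped
reads in millions) is attached when placements are supplied. rpkm and
locus calls are invariant to multiplying all counts by a constant, which
is property-tested.

## mRNA target calling and expression groups

Antisense gene rpkm divides count-weighted antisense transcript hits
(multimappers split evenly across their antisense hits) by mature
transcript length in kb and total mapped reads in millions. The
"total mapped reads" denominator (not raw reads) is a documented choice
consistent with the coverage normalization. A gene is a high-confidence
target when antisense rpkm is strictly over 10; exactly 10 is not a
target. Expression uses the published background rule: below 5 rpkm is
background, so "expressed" means rpkm >= 5.

Expression groups over germline stages M1-M7 operationalize the published
verbal grouping: `constitutive` = expressed in every one of M1-M7;
`meiosis_specific` = expressed in at least one of M5-M7 and none of
M1-M4; `other` = the rest. The original's exact grouping algorithm (and
its handling of genes eliminated by programmed DNA elimination) is
unstated; this rule is the package's own and is stated here rather than
claimed as a reconstruction.

Metagene profiles drop each antisense read's 5' end — which pairs with
the 3'-most mature-transcript position the read covers — into one of
B = 50 equal bins along the transcript (5' to 3' of the mRNA), pooling
count-weighted mass over the gene set and normalizing to sum 1. The 5'
bias ratio is first-quintile mass over last-quintile mass, capped at 100
when the last quintile is empty. Note that uniformly distributed *reads*
give a bias slightly below 1, because a read of length L cannot have its
5' end in the first L-1 transcript positions; the flat-profile check in
the tests therefore constructs uniform 5' ends directly.

Reported percentages (e.g. "~89% of expressed genes targeted") round to
the nearest integer, matching the style of the source statements.

## Comparative statistics

* Z-scores standardize each feature row across libraries with the
  population standard deviation (divisor n); "standard Z-score" does not
  specify the divisor, so the population form is fixed and documented.
  Constant rows become all-zero and are flagged.
* PCA of libraries uses its own deterministic transform rather than an
  external package's: log2(rpkm + 1), top 500 most-variable features,
  feature centering, SVD; the sign of each component is fixed by making
  its largest-magnitude loading positive, so output is bit-reproducible.
  Variance explained over all components sums to 100%, and full-rank
  back-projection reproduces the centered matrix (both tested).
* Venn region counts partition the union for 2 or 3 sets.
* The plasticity summary reports, per stage, the classified read-mass
  fractions on WAGO-repeats versus antisense mRNA and defines the switch
  stage as the first stage where the antisense-mRNA fraction exceeds the
  repeat fraction.

## The synthetic-data generator

`sim_config()` defaults define the study conditions: a 2 Mb genome (two
~1 Mb contigs plus a 20 kb mitochondrial contig), 300 spliced genes with
1-8 exons (exons 120-300 bp, introns 50-150 bp), 6 rRNA, 20 tRNA and 30
miRNA loci, and a 120-locus repeat catalog: 80 dispersed TE-like loci in
8 families of 10, each copy a family consensus with 2% per-base mutation
(guaranteeing multimapping reads), plus 40 tandem loci tiling a 120 bp
unit. Forty dispersed loci (4 whole families) are the planted enriched
subset; the tandem family is entirely cold, mirroring the observation
that the 120 bp tandem repeat is not small-RNA targeted. Repeat families
are aligned with the planted/cold split because, at 2% divergence, ~40%
of 22-mers cross-map within a family: a consensus shared between planted
and cold loci would leak planted coverage onto cold loci through the
fractional multimapper weights and make the planted/cold truth
ill-defined. Planted loci are drawn 500-2,000 bp (cold: 500-3,000 bp), so
the planted fold enrichment is ~30x under the default mixtures.

Features are placed by an exact free-list allocator with per-class
margins: repeat and blacklist-class (rRNA/tRNA/miRNA) loci keep >2,000 bp
from every neighbor so that a called locus can never merge across two
truth loci or into a blacklist locus by the 2,000 bp rule; genes pack
with a small 50 bp margin. Gene expression per stage is log-normal
(meanlog log 60, sdlog 0.7) for expressed gene-stages and uniform on
[0, 2] otherwise, arranged in constitutive (60%), meiosis-specific (20%)
and random-pattern (20%) genes.

Archetype libraries (`archetype_table()`) draw 200,000 reads per library
from mixtures over read sources (miRNA, repeat-antisense, mRNA-antisense,
mRNA-sense, intergenic, rRNA, tRNA, random). Lengths are a discretized
Normal(mode, 1) clipped to 18-30 nt with archetype modes 22 (input,
ALG1-, WAGO12-, NRDE3-like), 23 (WAGO3-like), 24 (CSR1-like) and 26
(ALG4-like). The first nucleotide follows the archetype bias (default
0.85 for G, or U for the miRNA archetype; the CSR1-like archetype carries
a 22% adenine minority) via bounded rejection sampling on the candidate
read's 5' base. The input archetype puts 85% of its mass antisense to
repeats (the published 80-90% bulk), 97% of repeat mass on planted loci
and 3% on cold ones. mRNA-antisense reads are sampled from spliced
transcript sequence — so some span junctions — with gene weights
proportional to expression; the NRDE3-like archetype switches its mixture
from repeat-dominant (0.75) to mRNA-dominant (0.60) at M5 and samples
late-stage 5' ends with a Beta(1, 3) position bias; the ALG4-like
archetype runs at 0.2% depth before M6 and targets meiosis-specific genes
afterwards. Archetype-specific gene pools apply to late mixtures; early
mixtures draw from genes expressed in the stage, which also reflects that
early ALG4 IPs resemble input. The stage-wise mixture values themselves
are the package's own defaults — the source describes the stage switches
qualitatively, and these numbers are conditions for testing, not claims
about the organism.

M8 (spermatid) libraries are deliberately different: a flat mixture over
all seven genomic sources plus one-eighth random sequences, with uniform
lengths 18-30 nt, emulating the degenerate, input-unlike profile of
spermatid IPs. A literal "uniform random sequences" library would
classify almost entirely as no-match on a 2 Mb genome (a random 18-mer
essentially never occurs), which would contradict the intended "no
dominant category" behavior; the flat-mixture design keeps every category
below ~15%.

What the generator does *not* emulate: sequencing errors, UMIs, adapter
artifacts, 5'-phosphate chemistry, expression correlation structure
between stages, or realistic genome composition (outside repeat families
the sequence is i.i.d. uniform). Passing tests therefore demonstrate the
pipeline's correctness and recovery behavior under clean, known
conditions — not robustness to base-calling noise or annotation error in
real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the default scale: 2 Mb
genome, 200,000-read libraries, 10 simulation seeds for the locus-caller
recovery suite (3 seeds in the acceptance script's summary, which reports
pooled precision/recall). Recovery checks use reciprocal >= 50% overlap
to match called loci to truth and Jaccard similarity for target-gene
sets. Seed-window thresholds use `>=` comparisons; merge distance uses
`gap <= D`; rpkm target calls use strict `>`. All randomness flows from a
single integer seed; reruns are byte-identical (checked down to md5
checksums of every written file).

## Known limitations

* Exact matching only; a mismatch-tolerant mode is a config hook left at
  0 because the original alignment settings are unstated.
* Strand-combined coverage; whether the original coverage was
  strand-specific is unstated, and the classifier retains strand only
  through transcript hits.
* The miRNA class is an interval overlap against provided mature-arm
  loci; no hairpin folding or miRNA discovery is attempted.
* The caller can report genuinely enriched antisense-mRNA windows as
  loci (they survive the blacklist, which covers only rRNA/tRNA/miRNA/
  mito); against a repeats-only truth set these count as false positives
  and are the main reason caller precision is slightly below 1 on
  synthetic data.
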