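---
title: "Constructing cohort-specific reference genomes for metagenome compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing cohort-specific reference genomes for metagenome compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortref)
```

## The method

Reference-based compressors store a read as a position on a reference plus
its differences. For metagenomes the obstacle is the reference itself:
samples are mixtures, cohorts differ in composition, and comprehensive
microbial databases are too large and redundant to serve as a compression
reference. `cohortref` builds a small reference tailored to one cohort by
letting a subset of the cohort's own reads vote, via alignment, for the
database genomes that actually occur in it.

The pipeline is a chain of simple, individually testable steps:

* **Catalog normalization.** Each database genome, however it was
  deposited (chromosomes, scaffolds, contigs), becomes a single uppercase
  sequence with every `N` removed. We read "assembly gap" as "`N`
  character": gap runs in scaffolds are `N` runs, and removing *all* `N`s
  (not only long runs) guarantees the emitted reference is `N`-free, which
  both the built-in aligner and the codec rely on. Non-`N` IUPAC ambiguity
  codes are kept — they stand for real, if uncertain, sequence, and
  deleting them would shift genuine coordinates. Normalization is applied
  uniformly, also to genomes already deposited as single chromosomes
  (which it leaves unchanged apart from case and any stray `N`s).
  Concatenation follows record order with no separator; a read that
  happens to span a segment junction can therefore align across it, which
  we accept as a knowable artifact of desk-scale testing rather than
  insert artificial spacers into the reference.

* **Read QC.** A read is kept iff it is at least `read_min_len = 60` bases
  long and contains at most `max_n_bases = 0` `N`s. These are the two
  read-level rules the rest of the pipeline assumes; adapter and quality
  trimming are left to dedicated external tools.

* **Post-alignment filtering.** A mapped record survives iff `MAPQ >=
  mapq_min` (default 5), its CIGAR contains none of the forbidden
  operations `I, D, N, S, H` (leaving only the match operations `M`, `=`,
  `X`), and its mismatch count (NM tag) is at most `max_mismatches`
  (default 3). Because indel-containing CIGARs are already discarded, NM
  equals the substitution count on every surviving record, so `=`/`X`
  CIGARs need no special handling. A mapped record without an NM tag is an
  error, not a silent zero. Filters are applied per record *first*; then
  one best record per read is kept, ordered by alignment score (AS tag;
  records lacking one rank below any scored record), then fewer
  mismatches, then lexicographically smallest `(genome_id, pos)`. The
  chain is fully deterministic, so counts are reproducible regardless of
  SAM record order. Real aligners assign low MAPQ to multi-mapped reads,
  which makes the MAPQ filter and best-alignment selection interact;
  we keep the two stages in this order and expose every threshold in
  `filter_config()` so callers can match their aligner's conventions. The
  built-in test aligner sidesteps the interaction by emitting MAPQ 60
  everywhere.

* **Ranking.** mapping rate(g) = best-surviving reads on g / total reads.
  The denominator is the number of QC-passed reads given to the aligner
  — the natural reading of "total reads" at the point in the pipeline
  where alignment happens. Paired mates count as two independent reads in
  both numerator and denominator; no proper-pair constraint is imposed.
  Cross-sample aggregation is pooled counts (sum of numerators over sum of
  denominators), not a mean of per-sample rates: pooling weights samples
  by their sequencing depth and is robust to shallow samples, and it makes
  aggregation associative — pooling any partition of the samples gives
  identical results, which the tests exercise. Genomes with zero mapped
  reads carry no ranking information; they are excluded from the ranking
  proper and used only to pad when fewer than N genomes have nonzero
  counts (in `genome_id` order, with a message). Ties anywhere — including
  at the N-th boundary — break by `genome_id` ascending.

* **Sub-database splitting.** When the database must be aligned against in
  pieces (memory limits), `split_catalog()` partitions genomes by
  deterministic greedy balancing on total bases (largest genome first into
  the lightest bin; ties by `genome_id`), since index memory scales with
  bases, not genome count. Each pass keeps each read's best surviving
  record; `merge_subdb()` re-runs the same best-record ordering across the
  per-sub-database winners. Because the ordering is total and
  deterministic, the merged counts equal a monolithic run by construction,
  and an acceptance test verifies the equality exactly on a 30-genome
  community split three ways.

## The built-in aligner

Production alignment belongs to Bowtie2/BWA/Minimap2; the package consumes
their SAM. The built-in aligner exists so the pipeline can be exercised
hermetically. It is deliberately simple: exact-match seeding on
non-overlapping k-mers of the read (default `seed_length = 21`), plus one
k-mer anchored at the 3' end, on both strands, against a hash index of all
catalog k-mers; every candidate locus is extended by full-read Hamming
comparison (ungapped, no base-quality model) and reported with `cigar =
"<len>M"`, `mismatches` = Hamming distance, and `align_score = len - 5 *
mismatches`. With at least `floor(len/k)` seeds, the pigeonhole principle
guarantees every locus with fewer mismatches than seeds is found: for
100-base reads and k = 21, every locus within the pipeline's 3-mismatch
budget. An acceptance test checks exact agreement with an exhaustive
offset/strand scan (via `Biostrings::matchPattern`) for all hits with at
most 3 mismatches. The score slope of -5 per mismatch only needs to order
candidate loci sensibly (it mirrors common mismatch penalties); MAPQ is a
constant 60 so the MAPQ filter never interferes with what the tests mean
to probe.

## The codec

The compression demonstrator encodes each read against the emitted
reference: the best hit with at most `max_diffs = 3` substitutions (the
same budget as the alignment filter) becomes `(genome, 1-based position,
strand, substitution list)`; anything else falls back to the raw sequence.
Decoding takes the reference substring, reverse-complements it on the
minus strand, and applies the substitutions — lossless by construction,
property-tested on reads including reverse-strand, N-containing and
unmappable ones. The container holds a reference MD5 checksum (decoding
with a different reference is refused), varint-coded integers, 2-bit
packed raw ACGT sequences (plain bytes when a read contains other
letters), and is finished with a gzip entropy stage. Read ids and quality
strings pass through to the entropy stage untransformed: the reference
choice affects only the sequence stream, and quality scores are known to
dominate FASTQ size and resist compression, so the codec's ratios measure
exactly the part of the problem the cohort reference can influence. The
ratios are therefore not comparable to full-featured tools like Genozip,
which model all three streams; Genozip is available as an optional
external adapter and is never a test dependency.

## The synthetic-data generator

The generator is the package's study design, with defaults chosen once:

* genomes are i.i.d. uniform ACGT (no repeats, no shared k-mers beyond
  chance, no GC structure) — 20 genomes of 100 kb in the ranking study;
* abundances are lognormal(0, sigma) with `sigma = 1.5`, normalized and
  sorted. This reproduces the qualitative skew of real communities, where
  a small minority of species carries most of the abundance (the
  abundant-species proportion — the fraction of species needed to reach
  80% of total abundance, boundary species included — typically lands
  well below 0.5 at these defaults, 0.2–0.4 in the worked examples);
* reads are 100-base pairs from fragments of 300 ± 30 bases (mate 1
  forward, mate 2 reverse), substitution errors i.i.d. at 0.5% per base;
  1-base indels and N bases are injected only as explicit knobs
  (`indel_read_fraction`, `n_base_fraction`, both default 0) to exercise
  the CIGAR and QC filters, since the pipeline discards such reads anyway.
  Truth positions are 1-based on the normalized genome, matching SAM.

What passing tests show, and what they do not: recovery of the true
most-abundant genomes demonstrates that counting, pooling, ranking and
selection are correct under a known model with genomes that are
unambiguous to assign. Real communities add conserved regions and shared
k-mers between related genomes (multi-mapping), uneven coverage, error
spectra that vary along the read, and database genomes that are imperfect
representatives of the strains actually present — none of which the
generator emulates. The tests validate the pipeline's logic, not its
behavior under homology.

## Numerical and interface choices

* Mapping rates are exact ratios of integer counts; the table invariant is
  checked to 1e-12 and prefix sums (saturation curves) are monotone by
  construction. The abundant-species threshold comparison uses a 1e-9
  slack so that abundances like 4 x 0.2 reach 0.8 despite floating-point
  accumulation; a species exactly reaching the threshold is included.
* `simulate_reads` requires genome lengths above `insert_mean + 4 *
  insert_sd` so fragments always fit; inserts are clamped to at least the
  read length and at most the genome length. Rates are validated to
  [0, 1): "drop everything" scenarios are expressed as 0.999, which at any
  realistic read count rounds to all reads.
* Degenerate inputs fail loudly with classed errors
  (`cohortref_invalid_input`, `cohortref_parse_error`,
  `cohortref_io_error`, `cohortref_corrupt_stream`,
  `cohortref_tool_absent`): empty segment lists, genomes that are all gap,
  non-IUPAC characters (named with their segment index), duplicate ids,
  alignments naming genomes outside the catalog, containers whose
  checksum does not match, absent external binaries.
* The catalog's FASTA I/O (80-column wrap, gzip transparency) and reverse
  complementation are delegated to Biostrings. Plain-text SAM is parsed
  natively: only six mandatory columns plus two optional tags are needed,
  and keeping the reader native lets every fixture live as generated
  plain text.
* The CLI is a thin dispatcher over the exported functions (one Rscript,
  subcommands mirroring the pipeline stages) and returns exit statuses
  rather than calling `quit()`, so it is testable in-process.

## Problem sizes

The test suite and `scripts/acceptance.R` run the study at sizes chosen to
make the statistical checks decisive while staying desk-scale: the ranking
study uses 20 genomes x 100 kb with 5 samples of 50,000 pairs (the fixed
profile's rank-5/6 abundance gap of ~0.07 is two orders of magnitude above
the binomial sampling noise at that depth, so recovery failures would
indicate logic errors, not bad luck); the aligner oracle uses 5 genomes x
5 kb and 500 reads; the codec round-trip uses 10,000 reads; the acceptance
study uses a 30-genome database with a 20-species community, 5 x 20,000
pairs for construction and 20,000 held-out pairs for compression.

## Limitations

Beyond the generator's idealizations listed above: the built-in aligner is
ungapped and quality-blind, so it is a test instrument, not a production
aligner; the codec compresses only the sequence stream; long reads
(third-generation data) are out of scope; and the package does not choose
*which* samples to use for construction — callers decide, the functions
aggregate whatever they are given.
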