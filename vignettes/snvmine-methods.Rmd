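---
title: "snvmine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snvmine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

snvmine mines single nucleotide variations (SNVs: SNPs plus short indels)
from reads mapped against a reference transcriptome of unigenes, tags each
call with a battery of marker-selection filters, and estimates per-SNV
polymorphism by accession counting. This vignette explains the models and
procedures, the parameters that matter, the synthetic-data generator that
backs the test suite, and the design decisions taken where more than one
reasonable choice existed.

## Read cleaning

Reads (id, bases, per-base Phred qualities, platform class `short` or
`long`) pass through adaptor removal, quality trimming, and a length
filter.

**Quality trimming.** The default trimmer is the modified-Mott running-sum
algorithm: each base scores `quality − threshold`, and the contiguous
segment with the maximal, strictly positive cumulative score is kept. This
is the standard behaviour class of quality trimmers, it is deterministic,
and it admits an exhaustive O(n²) oracle, which the test suite exploits on
reads up to 200 bases. Ties between equal-scoring segments are broken to
the leftmost start, then the longest segment, so output never depends on
traversal order. A segment scoring exactly zero (every base exactly at the
threshold, with nothing above) is not kept: a read with no strictly
positive segment comes back empty rather than raising an error. The
alternative `sliding_window` mode clips from each end until a window of
width 4 reaches mean quality ≥ threshold; the retained span runs from the
first qualifying window's start to the last one's end, so up to three
below-threshold bases may survive at each end — the standard behaviour of
windowed trimmers. Both modes are idempotent and always return a
contiguous slice of the input.

**Adaptor removal** finds the best gap-free placement of each adaptor
inside the read, allowing mismatches up to `floor(rate × adaptor length)`
(default rate 0.1). The adaptor span is removed and the longer flank kept,
with ties keeping the 5' flank; removal repeats until no hit remains so
contamination at both ends is handled. Vector screening against a
database is out of scope; adaptor trimming covers the implementable part.

**Defaults.** Threshold 20 (the conventional 1%-error reliability floor)
and minimum lengths of 40 (short reads) / 100 (long reads) are package
defaults, tunable in the project configuration — they are conventional
values, not claims inherited from any particular dataset.

Cleaning statistics use the inclusive-median (Tukey hinge) quartile
convention via `stats::fivenum`, making the per-position boxplot numbers
bit-reproducible.

## Pileups and SNV calling

`build_pileups()` walks each alignment's CIGAR. Aligned bases become
observations at their reference column; an insertion is attached to the
column of the base to its left and a deletion to the column of its first
deleted base. The base quality recorded for an indel observation is the
quality of the flanking (preceding) read base — the evidence for an
indel lives at its junction, and the flanking base is the closest
measured proxy; this choice is deliberately simple and is flagged because a
fixed penalty would be an equally defensible alternative. Observations
whose base call is `N` are discarded. Accession and library labels come
from the `SM` and `LB` fields of the alignment read groups; alignments
without an accession label are kept under the accession `"unknown"` with a
warning rather than dropped.

**Calling rules.** At each column:

1. observations with mapping quality `< 15` are not considered
   (`min_map_qual`, configurable);
2. remaining observations are grouped by allele; reference-matching bases
   form the reference allele;
3. each allele is scored from the qualities of its three most reliable
   reads: `PQ1 + 0.25 (PQ2 + PQ3)` with `PQ1 ≥ PQ2 ≥ PQ3`. With two
   observations the score degrades to `PQ1 + 0.25 PQ2`, with one to `PQ1`;
   the formula never disqualifies a low-coverage allele outright, which
   matters for transcriptome studies where a few-fold coverage is common;
4. alleles with score ≥ 20 (`min_allele_qual`) are retained, and a column
   with two or more retained alleles becomes an SNV. The reference allele
   counts toward the two-allele requirement — otherwise an ordinary
   biallelic ref/alt site could never be called.

The allele-quality threshold of 20 is the conventional Phred reliability
floor; the mapping-quality cutoff of 15 is the calling rule's standard
value. Both are explicit fields of `caller_config()`.

A position where retained alleles mix substitutions and indels is typed
`complex`; the marker-kind filter (VK) deliberately treats it as neither
SNP nor indel.

**VCF.** Internal coordinates are 0-based half-open; VCF output is
1-based, with indels anchored on the preceding reference base per VCF
convention (a variant at the very start of a unigene anchors on the right
instead). Every applied filter appears as a FILTER header line; records
failing filters list them, records passing all applied filters say PASS,
and unfiltered records carry `.`. Allele qualities, read counts and the
per-accession / per-library / per-platform supporting counts are written
to declared INFO fields, making the records lossless: parsing a written
file reconstructs the full call objects, and rewriting the parsed records
reproduces the file byte for byte.

## The nine selection filters

Filters are pure predicates that tag records and never delete them, so
application order is irrelevant and the record count is conserved. Pass
conditions (defaults in parentheses):

| tag | pass condition |
|-----|----------------|
| MAF | most-frequent-allele read frequency in the pool accessions `< 0.80` |
| HVR | unigene divergence `≤ 4` percent |
| UCR | no hit in the unigene similarity report |
| I30 | distance to every intron/exon boundary `> 30` |
| CL  | distance to both unigene ends `> 30` |
| CS  | distance to the nearest other SNV `> 60` |
| CEF | some enzyme site count differs between alleles (CAPS) |
| VK  | the SNV is of the selected marker kind |
| GF  | most-frequent-allele read frequency in the selected libraries `< 0.67` |

Design notes:

* **Exact arithmetic.** Frequency comparisons are done by integer
  cross-multiplication against the threshold's decimal expansion, so
  boundary cases are unambiguous: 2 of 3 reads gives 2/3 = 0.666…, which
  *is* below 0.67, regardless of floating-point representation.
* **HVR divergence** is defined as `100 × (SNVs on the unigene) /
  (unigene length)`. An alignment-mismatch-rate definition would be an
  alternative; SNV density was chosen because it is computable from the
  call set alone. All called SNVs (not only those passing other filters)
  enter the density, and likewise the CS neighbour distance.
* **MAF vs GF.** Both are read-count frequencies; they differ only in the
  label set they restrict to (accession pool vs library set). Read counts
  rather than accession counts are used because the filter is motivated by
  pooled-library designs in which balanced allele ratios are expected in
  the reads themselves. Empty pool/library sets mean "all".
* **UCR** consumes a precomputed two-column similarity report
  (`unigene_id`, `flag`) standing in for a sequence self-comparison, which
  keeps the package self-contained; unigenes absent from the report are
  treated as hit-free with a warning.
* **CEF** substitutes each allele into the unigene sequence and counts
  IUPAC-site matches within `flank_len = 60` bases of the column. All
  allele windows share the same outer reference coordinates (the flanks
  are taken around the longest replacement span at the column), so a
  count difference can only come from the alleles, never from unequal
  window extents. Windows truncate at unigene ends. Sites are matched on
  the given strand only; nearly all shipped sites are palindromic, so the
  restriction is minor. The shipped table holds ~30 common 4–6-cutters
  and is a plain editable TSV.
* **Boundary semantics** follow the printed comparisons exactly: strict
  `<` for frequencies, inclusive `≤` for HVR, strict `>` for distances, so
  a boundary distance of exactly 30 fails I30 while 31 passes.

## Polymorphism by accession counting

Sequence collections convey genotype information from many accessions, so
a crude polymorphism estimate counts, per retained allele, the distinct
accessions supporting it. The most-common-allele frequency is
`max(set size) / sum(set sizes)`, and PIC is computed from those
accession-count frequencies as expected heterozygosity `1 − Σ pᵢ²`. The
second-order Botstein form (`1 − Σpᵢ² − Σ_{i<j} 2pᵢ²pⱼ²`) is provided as
an option; heterozygosity is the default because with the small accession
counts involved the extra term suggests more precision than the data
carry. Accession counts, not read counts, feed PIC — read depth reflects
expression, not population frequency.

Set classification: an SNV is *variable* on a platform when ≥ 2 of its
alleles have observations from that platform; SA = variable only among
long (Sanger-class) reads, IL = only among short reads, CO = both. These
three are mutually exclusive and exhaustive over SNVs variable on at least
one platform. PO flags SNVs observed in ≥ 6 accessions whose
most-common-allele frequency is `< 0.67` (exact arithmetic again), and is
independent of the platform partition. HL (pass MAF ∧ HVR) and EU (HL ∧
UCR ∧ I30 ∧ CL) are expressed as conjunction queries over the tag matrix
rather than separate code paths. A genotyped panel is called polymorphic
for a marker when its most frequent allele stays below 0.95.

## The synthetic-data generator

`simulate_project()` materializes a complete study: random unigenes,
per-accession haplotypes with planted variants, platform-specific reads,
coordinate-sorted alignments, intron annotations, a similarity report and
an enzyme table, all with ground-truth sidecars, and byte-identical under
a fixed seed (each generator draws from its own seed offset, so stages
are individually reproducible).

Default conditions describe a small transcriptome resequencing study: 20
unigenes of 900–1100 bp, 8 accessions, 400 short reads (75 bp, ≈ 30×) and
13 long reads (400 bp, ≈ 5×) per unigene, variant rate 0.01/bp with 10%
indels of 1–3 bp, allele frequency spectrum {0.5, 0.25, 0.125}, 0.5%
sequencing error, and 10% of alignments assigned mapping quality below
15 to exercise the caller's exclusion rule. Planted variants keep ≥ 4 bp
spacing and ≥ 5 bp distance from unigene ends so deletion spans stay
disjoint and VCF anchoring is always well defined; the resulting loss
relative to a pure Bernoulli draw is small (a few percent) and the planted
count stays within the binomial 3σ band the tests assert.

**Error model.** Mean base quality decays linearly along the read (38→22
for short reads, 35→20 for long, Gaussian noise sd 3–4), qualitatively
emulating real per-position quality profiles. Substitution errors are
placed with probability proportional to `10^(−q/10)` — errors concentrate
where the recorded confidence is low — and an erroneous base's recorded
quality is resampled from 2–12. The generator therefore emulates a
*calibrated* base caller: wrong calls carry sub-threshold confidence.
This is the idealization that makes the planted-recovery tests a test of
the caller's threshold logic; real base callers are imperfectly
calibrated, occasionally reporting high confidence on wrong bases, and on
real data the false-call rate is correspondingly higher than on these
fixtures. Passing the recovery tests demonstrates that the exclusion and
scoring rules work as specified, not that the pipeline is robust to
miscalibrated qualities. Homopolymer-specific error models and
colour-space encodings are likewise not modelled; all short reads are
base-space.

**Alignments** place each read at its true origin with a CIGAR derived
from its haplotype's planted indels (read ends are nudged onto
reference-mapped bases, so no clipping is needed). This isolates the
caller from mapping error by construction; mapping itself is a separate
concern supplied by the user's SAM/BAM.

## Projects and reproducibility

`create_project()` writes a directory with a YAML configuration carrying
every default threshold; unknown sections or keys are rejected to catch
typos. `analyze()` runs the stages clean → call → filter → stats, each
reading and writing only standard-format files under the project
directory, so any stage is an entry point — a project holding only a VCF
can run the filter stage directly. Identical configuration, inputs and
seed give byte-identical VCFs and tag tables. The `threads` argument is
accepted for interface compatibility; work units are processed serially
in deterministic reference order, so results are independent of its value
by construction. A project log records the package version, configuration
hash and per-stage record counts.

Exit codes of the `exec/snvmine` command-line wrapper: 0 success, 2
configuration error, 3 missing input, 4 format error.

## Problem sizes used by the tests

The test suite verifies the formula and caller against independent
reimplementations (10,000 random quality lists; 1,000 random pileup
columns), the trimmer against exhaustive search (500 reads ≤ 200 bp), the
nine filters against brute-force oracles (> 1,000 randomized instances
plus the printed boundary cases), VCF round-trips on 500+ called SNVs,
set classification on a 300-SNV planted cohort, and planted-variant
recovery on the default study above, where the package recovers 100% of
truth variants supported by ≥ 3 reads per allele with no false calls.
Determinism is asserted by running full analyses twice at different
thread settings and comparing bytes. These sizes were chosen so the whole
suite completes in a few minutes on one CPU while each property is still
exercised at a scale where failure modes would surface.

## Known limitations

* No genotype likelihoods, diploid models, base-quality recalibration or
  realignment: the caller consumes alignments as given.
* Allele quality for indels leans on flanking-base quality (see above).
* The similarity report is an input, not a computed self-comparison.
* PIC from accession counts is a crude polymorphism index — with few
  accessions it is dominated by sampling noise, which is precisely why
  the PO set also requires ≥ 6 accessions.
* Primer design, melting-curve predictability and other assay-specific
  concerns are out of scope; CEF only asserts that a differential
  restriction site exists.
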