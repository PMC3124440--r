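# snvmine

SNV calling and marker selection from transcriptome read pileups.

## The problem

Resequencing a transcriptome across many accessions (plant lines,
cultivars, landraces) yields thousands of candidate single nucleotide
variations — SNPs and short indels, collectively SNVs. Only a fraction of
them are worth taking to the genotyping bench: calls must be reliable at
the modest coverage transcriptome studies afford, technically easy to
assay (away from intron boundaries, unigene ends and neighbouring SNVs,
not buried in gene families), and actually polymorphic across the
material to be genotyped. snvmine implements that whole selection
funnel for researchers and breeders working on non-model species.

## The method

**Calling.** Reads mapped to a reference transcriptome of unigenes
(SAM/BAM with read groups carrying accession and library labels) are piled
up per position. Reads with mapping quality `< 15` are excluded. Each
allele at a column is scored from its three most reliable supporting
reads,

```
allele quality = PQ1 + 0.25 (PQ2 + PQ3),   PQ1 ≥ PQ2 ≥ PQ3,
```

and a position with two or more alleles scoring ≥ 20 (the reference
allele counts) is reported as an SNV in VCF, with all supporting counts
in INFO fields.

**Selection.** Nine filters tag — never delete — each call:
most-frequent-allele frequency in a pool `< 0.80` (MAF), unigene
divergence `≤ 4 %` (HVR), no similarity hit (UCR), distance `> 30` to
intron boundaries (I30) and unigene ends (CL), `> 60` to the nearest SNV
(CS), detectability by restriction digestion (CEF, CAPS markers), marker
kind (VK), and library-restricted frequency `< 0.67` (GF). Frequency
boundaries are decided in exact rational arithmetic (2/3 passes a 0.67
bound). Tags land in the VCF FILTER column.

**Polymorphism.** Counting the accessions in which each allele appears
gives a crude polymorphism estimate per SNV: the most-common-allele
frequency, PIC (`1 − Σpᵢ²` over accession-count frequencies), the
platform sets SA/IL/CO (variable among long reads only, short reads only,
or both), the polymorphic set PO (≥ 6 accessions, max-allele frequency
`< 0.67`), and the preset selections HL (MAF ∧ HVR) and EU (HL ∧ UCR ∧
I30 ∧ CL).

A deterministic simulator generates complete synthetic studies —
unigenes, planted per-accession variants, reads with decaying quality
profiles, alignments, annotations — plus ground-truth tables, and backs
the entire test suite.

## Worked example

Simulate a small four-unigene study, call, filter and summarize:

```r
library(snvmine)

cfg <- simulation_config(n_unigenes = 4, unigene_len_range = c(400, 500),
                         reads_per_unigene = c(short = 120, long = 6),
                         read_len = c(short = 75, long = 300), seed = 7)
p <- simulate_project(cfg, "demo")

reference <- Biostrings::readDNAStringSet(p$reference)
pileup    <- build_pileups(read_alignments(p$alignments), reference)
snvs      <- call_snvs(pileup, caller_config())
snvs
#> <snv_set: 22 variants>

contexts <- build_contexts(reference, snvs, gff_path = p$gff,
                           similarity_path = p$similarity)
tagged   <- apply_filters(snvs, contexts, filter_config(vk_kind = "any"))
head(snv_table(tagged)[, c("unigene", "pos", "kind", "alleles",
                           "n_accessions", "mcaf", "pic", "CO", "PO")])
#>      unigene pos  kind alleles n_accessions  mcaf   pic    CO    PO
#> 1 unigene001  34   snp r:A,s:T            7 0.714 0.408 FALSE FALSE
#> 2 unigene001 284   snp r:T,s:G            8 0.500 0.500  TRUE  TRUE
#> 3 unigene001 358   snp r:A,s:C            8 0.500 0.500  TRUE  TRUE
#> 4 unigene001 476 indel r:C,i:C            5 0.833 0.278 FALSE FALSE
#> 5 unigene002  32 indel r:A,i:C            6 0.750 0.375  TRUE FALSE
#> 6 unigene002  89   snp r:T,s:A            7 0.857 0.245 FALSE FALSE

sum(marker_sets(snv_tags(tagged))$HL)
#> [1] 11
```

Each row is one called SNV: its alleles (`r:` reference, `s:`
substitution, `i:` insertion), the number of accessions it was seen in,
the most-common-allele frequency and PIC from accession counts, and its
set flags — here the two balanced SNPs seen in all eight accessions are
both common to the platforms (CO) and polymorphic (PO), and 11 of the 22
calls form the high-likelihood (HL) set. `write_vcf(tagged, "out.vcf")`
writes the annotated calls.

The same workflow is available as a two-command project interface
(`create_project()` then `analyze(dir, stage = "all")`, or the
`exec/snvmine` script), driven by one YAML configuration holding every
threshold above.

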