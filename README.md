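# ncmapr

Proteogenomic annotation of noncanonical MHC class I–associated peptides
(ncMAPs) in R.

Immunopeptidomics routinely sequences peptides that match no annotated
protein. A large fraction of these come from "noncoding" parts of
protein-coding genes — 5'UTRs translated from near-cognate start codons,
retained introns, 3'UTRs, and exons read in an alternative frame — and some
are selective enough for tumours to be attractive T-cell therapy or vaccine
targets. `ncmapr` implements the post-identification half of that analysis:
it takes peptide lists (e.g. from de novo sequencing) plus a genome,
annotation and proteome, and answers *where in the genome each peptide can
come from, by what mechanism, and whether it looks cancer-selective*.

## What it computes

* **Pre-mRNA 3-frame translation (3FT) search space.** Every protein-coding
  gene's unspliced sense pre-mRNA is translated in frames 0/1/2 and split at
  stop codons into clean segments with coordinate-recoverable FASTA headers
  (`>3FT|gene|chrom|strand|frame|anchor|index`), so any matched peptide maps
  back to exact genomic coordinates.
* **Sequential classification.** A peptide is *canonical* if it matches a
  proteome window with at most one isobaric Leu/Ile interchange (`hard = 0`,
  `li ≤ 1`); otherwise *noncanonical* if it occurs verbatim in the 3FT
  space **and** sits at least 3 mismatches (Hamming, exhaustive window scan)
  from every known protein; otherwise *unmapped*.
* **Genome mapping and feature annotation.** Noncanonical peptides are
  emitted as BED6 and labelled `five_prime_utr` / `intronic` /
  `three_prime_utr` / `exonic_alt_frame` per transcript (labels are not
  mutually exclusive).
* **Mechanistic explanation.** Upstream in-frame scans for near-cognate
  start codons (ATG, CTG, TTG, GTG, ACG) with 203-nt
  translation-initiation-site windows and a pluggable TIS scorer; an
  intron-retention test that propagates the reading frame across exons and
  asks whether an intronic peptide is in frame with its upstream exon
  (`(peptide 5' start − in-frame coordinate) mod 3 = 0`); and a frameshift
  module that builds mutant proteins from coding indels (VCF) and matches
  peptides against their novel C-terminal tails.
* **Cohort comparison.** Strand-aware genomic overlap of peptide sets with
  a minimum-overlap rule (default 21 nt = 7 aa), with exact per-peptide
  shared/exclusive counts.
* **Cancer-selectivity triage.** Three ordered filters: detection in a
  panel of normal immunopeptidomes; parent-gene 90th-percentile expression
  ≥ 1 TPM in any healthy tissue (testis excluded as immune-privileged);
  any healthy-tissue protein evidence. Peptides passing all three are
  `cancer_selective`. Plus an HLA binding-matrix utility (EL rank ≤ 0.5%
  strong binders, pairwise cosine distances between allele profiles).
* **De novo score calibration.** The minimum confidence threshold whose
  retained predictions reach a target whole-sequence accuracy (I/L
  equivalent), default 90%.
* **Synthetic fixtures.** A deterministic generator that plants peptides of
  every category (with generation-time verification of the ≥3-mismatch
  margin and the intron-retention frame condition) so the entire pipeline
  is testable without any download.

## Worked example

```r
library(ncmapr)
library(dplyr)

proteome <- c(ALBU = "MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGEENFKALVLIAFAQYLQQ")
threeft <- tibble::tibble(
  gene_id = "GENE42", chrom = "chr1", strand = "+", frame = 1L,
  segment_index = 0L, anchor = 1201L,
  aa_seq = "SLTRAFAPFPTQFNNKDE", length = 18L)

res <- classify_peptides(c("AFAPFPTQF", "TFISLLFLF", "WWWHHHKKK"),
                         proteome, threeft)
res %>% select(sequence, category, hard, li)
#> # A tibble: 3 × 4
#>   sequence  category      hard    li
#>   <chr>     <chr>        <int> <int>
#> 1 AFAPFPTQF noncanonical     7     0
#> 2 TFISLLFLF canonical        0     0
#> 3 WWWHHHKKK unmapped         7     0

peptides_to_bed(res, threeft)
#> # A tibble: 1 × 8
#>   chrom start   end name      score strand gene_id frame
#>   <chr> <int> <int> <chr>     <int> <chr>  <chr>   <int>
#> 1 chr1   1213  1240 AFAPFPTQF     0 +      GENE42      1
```

`AFAPFPTQF` occurs verbatim in the 3FT segment and is 7 mismatches from the
nearest proteome window, so it is noncanonical; its BED interval
(`1213 = anchor + 3·4`, 27 nt long) re-translates to the peptide.
`TFISLLFLF` is an exact proteome substring (canonical). `WWWHHHKKK` matches
nothing (unmapped).

The selectivity triage on the packaged table of 24 published candidate
peptides (parent-gene mean expression and healthy-tissue protein-evidence
counts):

```r
tab <- readr::read_tsv(system.file("extdata", "cancer_selective_candidates.tsv",
                                   package = "ncmapr"))
triage <- classify_selectivity(
  tab %>% transmute(peptide, gene_id = gene_name),
  panel = character(),
  expr = tab %>% distinct(gene_id = gene_name, tpm_q = mean_tpm) %>%
    mutate(tissue = "healthy_mean"),
  protein_evidence = tab %>% distinct(gene_id = gene_name,
                                      n_tissues = protein_tissues))
count(triage, label)
#> # A tibble: 2 × 2
#>   label                 n
#>   <chr>             <int>
#> 1 cancer_selective     17
#> 2 protein_expressed     7
```

17 of the 24 low-expression candidates have no parent protein evidence in
any of 56 healthy tissues and are called cancer-selective; the other 7
(e.g. histone genes with protein in 43–44 tissues) are excluded by step 3.

A full pipeline run is one call (or `exec/ncmap run -c config -o outdir`
from a shell):

```r
fx <- make_fixture(fixture_spec(seed = 42), dir = tempfile())
run_pipeline(list(genome = fx$paths$genome, gtf = fx$paths$gtf,
                  proteome = fx$paths$proteome, peptides = fx$paths$peptides,
                  vcf = fx$paths$vcf, expression = fx$paths$expression,
                  protein_evidence = fx$paths$protein_evidence,
                  panel = fx$paths$panel),
             out_dir = "ncmap_out")
```

which writes the 3FT FASTA, classification TSV, BED, feature/ORF/IR tables,
frameshift hits, selectivity labels and a JSON summary of per-stage counts.

## Vignette

`vignettes/noncanonical-peptide-annotation.Rmd` documents the model and its
assumptions: the exact mismatch semantics, the frame-propagation rule and
its validation against a splice-and-translate oracle, what the synthetic
fixtures do and do not emulate, and the package's numerical choices and
limitations.
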