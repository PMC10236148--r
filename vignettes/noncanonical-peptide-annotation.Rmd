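---
title: "Annotating noncanonical MHC class I peptides from the genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating noncanonical MHC class I peptides from the genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmapr)
library(dplyr)
```

## The problem

MHC class I molecules present 7–15-residue peptides sampled from the cell's
translational output. Mass-spectrometry immunopeptidomics recovers these
peptides, and a consistent minority of confidently sequenced peptides match
no annotated protein. Many of them are genuine translation products of
"noncoding" regions *within protein-coding genes*: upstream open reading
frames in 5'UTRs (often initiated at near-cognate codons), retained
introns, 3'UTRs read through, and exons decoded in an alternative frame.
Because such peptides are shared between patients rather than
mutation-specific, the cancer-selective subset is a candidate source of
off-the-shelf immunotherapy targets.

`ncmapr` covers the genomic half of this workflow: given peptide sequences
(typically from de novo sequencing upstream, which is out of scope here), a
genome, an annotation and a reference proteome, it builds the noncanonical
search space, classifies and maps the peptides, tests mechanistic
explanations, and triages cancer selectivity.

## The search space: pre-mRNA three-frame translation

The search space is deliberately the *unspliced* sense pre-mRNA of every
protein-coding gene, translated in all three frames. Unspliced, because the
mechanisms of interest (intron retention, UTR translation, alternative
frames) produce peptides that are contiguous in genomic, not spliced,
coordinates; sense-only, because antisense products would require evidence
the model does not use. Each frame translation is split at stop codons
(`*`) and ambiguous residues (`X`, from any codon containing `N`) into
maximal clean segments; segments shorter than `min_len` residues are
dropped. The default `min_len = 7` equals the shortest peptide the
classifier accepts — a shorter segment cannot contain a match, so the
default discards nothing relevant.

Every segment records an *anchor*: the genomic coordinate of the first base
of its first codon (for minus-strand genes, the genomically highest base of
that codon). A residue window `[aa_start, aa_start + aa_len)` of a segment
then maps to the genomic interval
`[anchor + 3·aa_start, anchor + 3·(aa_start + aa_len))` on the plus strand
and its mirror on the minus strand. All internal coordinates are 0-based
half-open; the 1-based closed GTF convention is converted once at load time
and BED output needs no further conversion. The FASTA header grammar
(`>3FT|gene|chrom|strand|frame|anchor|index`) makes the mapping recoverable
from the header alone; `parse_3ft_header(write_3ft_fasta(x))` is an exact
round trip, and the test suite re-translates emitted intervals back to
their peptides on both strands.

## Classification semantics

Tandem MS cannot distinguish leucine from isoleucine (the Xle pair), so
sequence comparison must treat I/L specially. `ncmapr` counts positionwise
differences in two classes: `li` (one residue is I, the other L) and `hard`
(everything else). The sequential rule is then:

1. **canonical** — best proteome window has `hard = 0` and `li ≤ 1`
   ("one mismatch allowed for the isobaric pair");
2. **noncanonical** — an exact 3FT substring hit exists (I and L
   distinguished here) *and* the minimum proteome distance
   `hard + li ≥ 3`;
3. **unmapped** — everything else, including the deliberate buffer zone of
   peptides with a 3FT hit but only 1–2 proteome mismatches. Because
   upstream identifications are never perfectly accurate, a 1–2-mismatch
   "noncanonical" call would too often be a slightly mis-sequenced
   canonical peptide; requiring three mismatches keeps the noncanonical
   set far from the proteome.

Two readings of the rules were possible: whether the `≥ 3` count includes
I/L interchanges, and whether the 3FT match tolerates them. We count
`hard + li` toward the threshold (a literal reading of both quoted rules
that contradicts neither) and keep the 3FT match exact; a documented
`xle_tolerant_3ft` flag enables one Xle mismatch for harmonising peptide
sets from other laboratories, which is the only context where it is
appropriate.

The proteome scan is an exhaustive substitution-only (Hamming) comparison
of the peptide against every length-matched window of every protein,
minimised lexicographically over `(hard + li, hard)`. At 7–25-mer scale
this is exact and deterministic where a heuristic aligner is neither;
insertions and deletions are intentionally out of contract (a gapped
"match" would not be the same peptide). Decoy and contaminant proteome
entries exist only for MS false-discovery control and are dropped before
the distance computation. The implementation is vectorised per offset and
is verified in the test suite against an independent plain-loop oracle;
no further speed machinery is needed at the package's documented problem
sizes (proteomes up to tens of kilo-residues).

## Feature annotation

Noncanonical peptides get one BED record per 3FT hit and are labelled per
transcript of their host gene: `intronic` if the interval intersects an
intron; `five_prime_utr` / `three_prime_utr` if it intersects the exonic
region 5' / 3' of the CDS extent (derived from the CDS when the GTF carries
no UTR features, since annotation dialects vary); and `exonic_alt_frame` if
it overlaps CDS whose codon grid differs from the peptide's. Frames are
compared as codon-start classes modulo 3 within each overlapped CDS exon,
so a peptide spanning a UTR/CDS junction out of frame receives both labels.
Labels are a union over transcripts with supporters reported — feature
categories of overlapping transcripts are genuinely not mutually exclusive,
and collapsing them would discard the ambiguity rather than resolve it.
Intersections require a single nucleotide of overlap, matching the interval
semantics of the standard genomic-ranges toolkits. A peptide whose frame
equals the CDS frame over its whole span receives no label at all: such a
peptide is a proteome substring and the classifier already called it
canonical.

## Upstream ORFs and translation initiation

For each noncanonical peptide the scanner walks 5'-ward from the peptide's
first codon in steps of three — only the peptide's own frame can produce
it — reporting every near-cognate start codon (ATG, CTG, TTG, GTG, ACG)
until the first stop codon, the reference edge, or the host gene boundary.
The gene-boundary default matches the gene-scoped search space; a
chromosome-wide scan is available by argument since the biology does not
stop at an annotation boundary. Every reported start therefore opens a
stop-free ORF containing the peptide, which the tests assert directly.

Each candidate start is packaged as a 203-nt window (100 nt of context on
each side, N-padded at reference edges, codon at positions 101–103) on the
coding strand — the genomic (pre-mRNA) context, consistent with the
unspliced search space, since initiation at these sites precedes or escapes
splicing-coupled checks. Scoring is delegated to a pluggable function
returning `[0, 1]`, positive strictly above 0.5. The bundled default is a
transparent position-weight heuristic over the Kozak consensus (purine at
−3, G at +4, minor positions, AUG bonus) scaled to `[0, 1]`. It is *not* a
trained initiation-site model and is labelled accordingly; it exists so
the pipeline runs end to end and ranks obviously good contexts above bad
ones, and any trained scorer with the same signature can be injected.

## Intron retention and reading frames

An intronic peptide is explicable by intron retention only if its codon
grid continues the upstream exon's reading frame. The package propagates
the frame across each transcript's exons in transcription order, starting
from the first exon's 5' end, and records per exon the *in-frame
coordinate*: the genomic position whose congruence class modulo 3 equals
the codon-start grid that a retained downstream intron would inherit. With
`L` the cumulative exonic length before the intron, the coordinate is
`exon 5' start − (L mod 3)` on the plus strand and the mirror on the minus
strand. A peptide with transcription-direction first base `p` inside the
intron is in frame iff `(p − coordinate) mod 3 = 0` (sign flipped on the
minus strand).

This rule is validated against an independent splice-and-translate oracle:
build the retained-intron transcript, locate the peptide in transcript
coordinates, and ask whether it starts on a codon boundary. The property
suite runs this comparison over randomly structured transcripts on both
strands and requires exact agreement. A published pseudocode variant of
this bookkeeping stores the remainder as `3 − leftover` and subtracts it
directly, which lands one base off the retained-intron grid for some exon
lengths and leaves the remainder stale when an exon ends on a codon
boundary; it is reproduced verbatim behind `method = "literal"` for
comparison, while the oracle-validated rule is the default. When several
transcripts share the intron, verdicts are reported per transcript plus an
any-transcript summary, mirroring the multi-label philosophy above.

## Frameshift mutant proteome

Coding indels whose length difference is not a multiple of three shift the
reading frame and create a novel C-terminal tail. From a minimal VCF
(CHROM/POS/REF/ALT plus a transcript id in INFO or a sidecar table) the
package validates each variant (REF must match the genome; in-frame indels
are rejected), locates it in spliced CDS coordinates strand-aware, applies
the edit, and translates: the *prefix* is every residue fully 5' of the
first codon touching the edit, the *tail* runs from that codon to the first
stop in the shifted frame. Downstream sequence for the tail is read through
the spliced transcript first and then the genomic 3' continuation (the
`readthrough = "genomic"` alternative reads straight through the unspliced
continuation; both are kept because published VCF-to-proteome tools do not
agree on this point, and the boundedness of the continuation is a
parameter). Peptide matching against mutants is exact with I/L
distinguished, and a hit must overlap at least one tail residue —
prefix-only matches are canonical evidence, already handled by the
classifier, not frameshift evidence. One modelling restriction: one simple
indel per record, no compound or phased variants, matching the per-record
structure of the mutation catalogues this analysis consumes.

## Cohort comparison

Peptide sets from different studies rarely match exactly — the same
presentation event yields longer, shorter or shifted sequences — so
comparison happens in genomic coordinates: a peptide is shared with another
set when some peptide there overlaps it by at least `min_overlap`
nucleotides on the same strand. The default 21 nt is three times the
shortest peptide length considered (7 aa). Counts are per original peptide,
not per merged cluster, and an `ignore_strand` flag reproduces the
behaviour of tools that drop strandedness. The implementation rides on
`GenomicRanges::findOverlaps(minoverlap = …)` and is verified against an
all-pairs loop; multi-set comparisons report both any-overlap and
all-overlap semantics because published pairwise figures do not say which
was used.

## Cancer-selectivity triage

Three filters in a fixed order, each labelling a peptide by its first
failure:

1. **Panel of normals** — exact sequence membership in peptides observed in
   healthy immunopeptidome samples (`non_cancer_selective_ms`).
2. **Transcript expression** — per (gene, tissue), the 90th percentile of
   sample-level TPM (linear interpolation by default, nearest-rank by
   flag; the published analyses do not state a method). If any parent gene
   reaches 1 TPM in any healthy tissue except testis — immune-privileged,
   hence exempt — the peptide is `expressed_above_cutoff`. The cutoff is
   applied per tissue on the percentile summaries, not on a mean across
   tissues: a mean would let one expressing tissue hide behind many silent
   ones. Printed "mean expression" columns in candidate tables are treated
   as display summaries.
3. **Protein evidence** — any parent gene with protein detected in at
   least one healthy tissue (testis again excluded from the counts) makes
   the peptide `protein_expressed`.

Peptides with several parent genes must pass steps 2 and 3 for *all* of
them (conservative AND): presentation cannot be attributed to one parent
over another, so every potential source must be silent. Missing genes are a
hard error by default (`missing_gene = "fail"` treats them as failing the
step instead, the conservative fallback for incomplete tables).

The HLA-side utility binarises an allele × peptide EL-rank table at the
strong-binder cutoff (rank ≤ 0.5%, inclusive) and computes pairwise cosine
distances between allele binding profiles. Cosine distance is a similarity
summary, not a metric (the triangle inequality can fail), which is fine
for its use here: ordination and visual comparison of binding motifs. A
t-SNE or similar embedding of the distance matrix is left to standard
libraries — it is visualisation, not contract.

## De novo score calibration

Given validation predictions with confidence scores and ground-truth
sequences, `calibrate_threshold()` picks the minimum score cutoff whose
retained set reaches the target whole-sequence accuracy (default 90%),
ties broken toward retaining more. Accuracy is whole-peptide equivalence
with I≡L and PTM annotations stripped — the calibration concerns backbone
identity, and residue-level accuracy (available by computing on your own
definition of `correct`) would answer a different question. If even the
top-scored subset misses the target the result is flagged unattainable
rather than silently returning the best effort. The chosen threshold is
verified against a full scan over all cutoffs in the tests.

## What the synthetic fixtures emulate — and what they do not

`make_fixture()` generates, from a single seeded random stream, a toy
genome (two chromosomes, up to 20 three-exon genes alternating strands,
one noncoding decoy gene), a proteome, peptide lists, a frameshift VCF,
and GTEx/HPA-style expression and protein-evidence tables, together with a
truth table. Plants per gene: canonical windows of the real proteins; a
5'UTR peptide behind a planted near-cognate start (with a stop codon
terminating the scan corridor so the expected hit list is exact); intronic
peptides placed on and off the retained-intron codon grid; a 3'UTR
peptide; an exonic peptide embedded in a shifted frame (re-checking that
the canonical frame stays stop-free); and deletion variants whose
junction-spanning tail peptides are recorded. Every noncanonical plant is
verified at generation time to sit ≥ 3 mismatches from every window of the
final proteome and to occur exactly once in the 3FT space, re-drawing
otherwise, so the planted truth is guaranteed by construction rather than
assumed. Expression designs straddle the 1 TPM cutoff with wide margins
(low ≈ 0.05 TPM log-normal, high ≈ 12 TPM in one tissue, testis-only
genes), and the designed percentile relations are asserted after drawing.

Fixtures are small by design — chromosomes of tens of kilobases, ≥ 200
planted peptides — so the full suite, including two fixture generations and
an end-to-end pipeline run, completes in about two minutes on one CPU; the
acceptance script's fixture run takes about half a minute. What passing
these tests shows is that the *logic* is exact: every planted configuration
is recovered with zero discrepancies. What it does not show: robustness to
messy real annotation (overlapping genes, patches, multi-transcript UTR
conflicts beyond what the union semantics cover), MS-level error modes
(the fixtures plant clean sequences, not spectra), or performance at
whole-genome scale, where the 3FT build dominates and would warrant
chunking. One interaction is worth knowing: a frameshift's shifted-frame
tail can legitimately contain an alternative-frame peptide planted in the
same gene, because both read the same genomic sequence in the same shifted
frame — the tests therefore check that planted tails are recovered and
that every reported hit is genuine, not that hit lists contain nothing
else.

## Numerical and degenerate-input choices

* Coordinates: 0-based half-open everywhere internally; GTF converted at
  load, BED written natively. The conversion is exercised by round-trip
  tests rather than trusted.
* Translation: standard code; codons with `N` become `X` and split
  segments (a peptide cannot be matched through an unknown residue);
  trailing partial codons are dropped; no selenocysteine handling.
* Genes with multiple spans per id are rejected at load — deterministic
  behaviour on toy and standard references beats silent mis-merging of
  haplotype duplicates.
* Empty inputs return typed empty tibbles, not errors; unknown
  chromosomes, out-of-range intervals, malformed 3FT headers, REF
  mismatches and scorers leaving `[0, 1]` are hard errors naming the
  offender.
* Ties: proteome windows tie-break on fewer hard mismatches at equal
  total; calibration ties break toward the larger retained set; BED output
  sorts on (chrom, start, name) for byte-stable files.
* `run_pipeline()` is a pure function of its inputs; reruns are
  byte-identical (tested), which is why no cache/resume layer was added at
  this scale.

## Limitations

The package classifies and explains peptides; it does not validate them.
Upstream concerns — spectral quality, FDR control, PTM localisation — are
assumed handled by the MS pipeline that produced the peptide list. The
bundled TIS scorer is a heuristic stand-in with the correct interface, not
a trained model. The selectivity triage is only as good as its expression
and protein-evidence tables, and its conservative AND over parent genes
will discard genuinely selective peptides with one broadly expressed
paralog. Finally, the 3FT space is gene-scoped by construction: intergenic,
antisense and long-noncoding sources are invisible to it, and peptides from
such regions will land in the unmapped bin.
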