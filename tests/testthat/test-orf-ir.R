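# hand-built plus-strand locus: [filler][TAA][CTG][safe]x2[ACG][safe]x1[PEP]
# with every planted codon in the peptide's frame
orf_locus <- function() {
  pep_nt <- "GCTTTTGCTCCTTTTCCTACTCAATTT"  # AFAPFPTQF
  up <- paste0("TAA", "CTG", "GAT", "CAT", "ACG", "GAT")
  chrom <- paste0(strrep("C", 50L), up, pep_nt, strrep("C", 50L))
  chrom_len <- nchar(chrom)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                          start = 40L, end = chrom_len - 10L)
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = 40L, end = chrom_len - 10L)
  list(ref = ref_from_tables(c(chr1 = chrom), genes, exons),
       pep_start = 50L + nchar(up), pep_end = 50L + nchar(up) + 27L)
}

test_that("scan_upstream reports in-frame near-cognate starts nearest first, stopping at stops", {
  loc <- orf_locus()
  iv <- list(chrom = "chr1", start = loc$pep_start, end = loc$pep_end,
             strand = "+")
  hits <- scan_upstream(loc$ref, iv, gene_id = "G1")
  expect_equal(hits$codon, c("ACG", "CTG"))  # nearest first
  expect_equal(hits$genomic_position, c(loc$pep_start - 6L,
                                        loc$pep_start - 15L))
  expect_equal(hits$upstream_offset_nt %% 3L, c(0L, 0L))
  # the TAA two codons above CTG terminated the walk before the gene start
})

test_that("a stop codon immediately upstream yields no hits", {
  chrom <- paste0(strrep("C", 60L), "TAG", "GCTTTTGCTCCTTTTCCTACTCAATTT",
                  strrep("C", 30L))
  chrom_len <- nchar(chrom)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                          start = 30L, end = chrom_len)
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = 30L, end = chrom_len)
  ref <- ref_from_tables(c(chr1 = chrom), genes, exons)
  iv <- list(chrom = "chr1", start = 63L, end = 90L, strand = "+")
  expect_equal(nrow(scan_upstream(ref, iv, gene_id = "G1")), 0L)
})

test_that("out-of-frame start codons between in-frame codons are not reported", {
  # in-frame: [CTG][AAT][GGA][PEP]; the AATGGA filler hides an ATG at an
  # offset that is not a multiple of 3 from the peptide start
  up <- paste0("CTG", "AATGGA")
  pep_nt <- "GCTTTTGCTCCTTTTCCTACTCAATTT"
  chrom <- paste0(strrep("C", 50L), "TAA", up, pep_nt, strrep("C", 30L))
  chrom_len <- nchar(chrom)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                          start = 40L, end = chrom_len)
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = 40L, end = chrom_len)
  ref <- ref_from_tables(c(chr1 = chrom), genes, exons)
  pep_start <- 53L + nchar(up)
  iv <- list(chrom = "chr1", start = pep_start, end = pep_start + 27L,
             strand = "+")
  hits <- scan_upstream(ref, iv, gene_id = "G1")
  expect_equal(hits$codon, "CTG")  # the off-frame ATG is invisible
})

test_that("tis_window is always 203 nt with the codon at positions 101-103", {
  fx <- cached_fixture()
  ref <- fx$ref
  w <- tis_window(ref, "chr1", 5000L, "+")
  expect_equal(nchar(w$sequence), 203L)
  expect_equal(substr(w$sequence, 101L, 103L), w$center_codon)
  # near the chromosome start: leading N padding
  w2 <- tis_window(ref, "chr1", 50L, "+")
  expect_equal(substr(w2$sequence, 1L, 50L), strrep("N", 50L))
  expect_equal(nchar(w2$sequence), 203L)
})

test_that("minus-strand windows agree with manual reverse-complement extraction", {
  fx <- cached_fixture()
  ref <- fx$ref
  pos <- 4000L
  w <- tis_window(ref, "chr1", pos, "-")
  manual <- substr(ref$chromosomes[["chr1"]], pos - 102L + 1L, pos + 101L)
  manual <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(manual)))
  expect_equal(w$sequence, manual)
  expect_equal(nchar(w$sequence), 203L)
})

test_that("score_tis applies the strict 0.5 positivity cutoff and validates the scorer", {
  w <- list(sequence = strrep("A", 203L), center_codon = "AAA")
  expect_true(score_tis(w, scorer = function(s) 1.0)$positive)
  expect_false(score_tis(w, scorer = function(s) 0.5)$positive)  # strict >
  expect_error(score_tis(w, scorer = function(s) 1.5), "\\[0, 1\\]")
})

test_that("the Kozak heuristic ranks a perfect context above a poor one", {
  perfect <- paste0(strrep("A", 94L), "GCCACC", "ATG", "G", strrep("A", 99L))
  poor <- paste0(strrep("A", 94L), "TTTTTT", "ATG", "T", strrep("A", 99L))
  expect_gt(kozak_scorer(perfect), kozak_scorer(poor))
  expect_gte(kozak_scorer(poor), 0)
  expect_lte(kozak_scorer(perfect), 1)
})

two_exon_ref <- function(strand, e1 = c(100L, 110L), e2 = c(200L, 210L)) {
  chrom <- random_dna(400L)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = strand,
                          start = e1[1], end = e2[2])
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
  ref_from_tables(c(chr1 = chrom), genes, exons)
}

test_that("exon_frame_table propagates the frame across exons (plus strand)", {
  set.seed(51)
  ref <- two_exon_ref("+")
  tab <- exon_frame_table(ref)
  # only the exon with a downstream intron is reported
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$inframe_coordinate, 100L)
  expect_equal(c(tab$intron_start, tab$intron_end), c(110L, 200L))

  # a 9-base first exon (length divisible by 3) leaves the next frame intact:
  # check via a 3-exon transcript where exon2 then starts in frame
  chrom <- random_dna(500L)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                          start = 100L, end = 350L)
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = c(100L, 200L, 300L),
                          end = c(109L, 212L, 350L))
  ref2 <- ref_from_tables(c(chr1 = chrom), genes, exons)
  tab2 <- exon_frame_table(ref2)
  expect_equal(tab2$inframe_coordinate[1], 100L)  # 9 nt, remainder 0
  expect_equal(tab2$inframe_coordinate[2], 200L)  # starts on a codon boundary
})

test_that("the literal pseudocode variant differs by its published remainder arithmetic", {
  set.seed(52)
  ref <- two_exon_ref("+", e1 = c(100L, 110L), e2 = c(200L, 210L))
  # frame-aware: one dangling base after a 10-nt exon -> coordinate 199
  # literal: remainder stored as 3 - leftover -> coordinate 198
  ref3 <- ref_from_tables(
    c(chr1 = random_dna(400L)),
    tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                   start = 100L, end = 310L),
    tibble::tibble(transcript_id = "T1", gene_id = "G1",
                   start = c(100L, 200L, 300L), end = c(110L, 210L, 310L)))
  aware <- exon_frame_table(ref3, method = "frame_aware")
  literal <- exon_frame_table(ref3, method = "literal")
  expect_equal(aware$inframe_coordinate[2], 199L)
  expect_equal(literal$inframe_coordinate[2], 198L)
})

test_that("exon_frame_table mirrors on the minus strand", {
  set.seed(53)
  ref <- two_exon_ref("-")
  tab <- exon_frame_table(ref)
  expect_equal(nrow(tab), 1L)
  # transcription starts at the genomically highest exon [200,210): its 5'
  # base 209 is the first codon start; the downstream intron is [110,200)
  expect_equal(tab$exon_start, 200L)
  expect_equal(tab$inframe_coordinate, 209L)
  expect_equal(c(tab$intron_start, tab$intron_end), c(110L, 200L))
})

test_that("intron_inframe applies the modulo-3 rule from the transcription 5' end", {
  rec <- tibble::tibble(transcript_id = "T1", chrom = "chr1", strand = "+",
                        exon_start = 90L, exon_end = 100L,
                        inframe_coordinate = 100L,
                        intron_start = 100L, intron_end = 200L)
  expect_true(intron_inframe(list(chrom = "chr1", start = 130L, end = 157L,
                                  strand = "+"), rec))
  expect_false(intron_inframe(list(chrom = "chr1", start = 131L, end = 158L,
                                   strand = "+"), rec))
  expect_true(intron_inframe(list(chrom = "chr1", start = 100L, end = 127L,
                                  strand = "+"), rec))
  expect_error(intron_inframe(list(chrom = "chr1", start = 300L, end = 327L,
                                   strand = "+"), rec),
               "does not intersect")
})

test_that("frame propagation agrees with the splice-and-translate oracle on random transcripts", {
  set.seed(61)
  for (rep in 1:100) {
    strand <- sample(c("+", "-"), 1L)
    n_exons <- sample(2:5, 1L)
    lens <- sample(9:40, n_exons, replace = TRUE)
    gaps <- sample(30:60, n_exons - 1L, replace = TRUE)
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- 50L
    for (k in seq_len(n_exons)) {
      starts[k] <- pos; ends[k] <- pos + lens[k]
      pos <- ends[k] + if (k < n_exons) gaps[k] else 0L
    }
    chrom_len <- pos + 50L
    genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = strand,
                            start = starts[1], end = ends[n_exons])
    exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                            start = starts, end = ends)
    ref <- ref_from_tables(c(chr1 = random_dna(chrom_len)), genes, exons)
    tab <- exon_frame_table(ref)
    expect_equal(nrow(tab), n_exons - 1L)
    for (r in seq_len(nrow(tab))) {
      rec <- tab[r, ]
      # which transcription-order exon is this record's upstream exon?
      upto <- r
      # probe three random positions in the intron
      for (probe in 1:3) {
        p5 <- sample(seq(rec$intron_start, rec$intron_end - 1L), 1L)
        iv <- if (strand == "+") {
          list(chrom = "chr1", start = p5,
               end = min(p5 + 3L, rec$intron_end), strand = strand)
        } else {
          list(chrom = "chr1", start = max(p5 - 2L, rec$intron_start),
               end = p5 + 1L, strand = strand)
        }
        got <- intron_inframe(iv, rec)
        want <- oracle_ir_inframe(exons, strand, upto, p5)
        expect_equal(got, want,
                     info = sprintf("strand %s rep %d record %d p5 %d",
                                    strand, rep, r, p5))
      }
    }
  }
})

test_that("exon_frame_table is invariant to the input row order of exons", {
  set.seed(62)
  chrom <- random_dna(500L)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                          start = 100L, end = 350L)
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = c(100L, 200L, 300L),
                          end = c(110L, 212L, 350L))
  ref_sorted <- ref_from_tables(c(chr1 = chrom), genes, exons)
  ref_shuffled <- ref_sorted
  ref_shuffled$exons <- ref_shuffled$exons[c(3L, 1L, 2L), ]
  expect_equal(exon_frame_table(ref_shuffled), exon_frame_table(ref_sorted))
})

test_that("upstream hits always open a stop-free ORF containing the peptide", {
  fx <- cached_fixture()
  cl <- cached_classification()
  bed <- peptides_to_bed(cl, fx$threeft)
  orf <- orf_scan(bed[1:25, ], fx$ref)
  for (i in seq_len(min(nrow(orf), 20L))) {
    h <- orf[i, ]
    iv <- bed[bed$name == h$name, ][1, ]
    if (iv$strand == "+") {
      span <- substr(fx$ref$chromosomes[[iv$chrom]],
                     h$genomic_position + 1L, iv$start)
    } else {
      span <- substr(fx$ref$chromosomes[[iv$chrom]], iv$end + 1L,
                     h$genomic_position + 1L)
      span <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(span)))
    }
    expect_false(grepl("\\*", translate_frame(span, 0L)),
                 info = paste(h$name, h$genomic_position))
  }
})
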