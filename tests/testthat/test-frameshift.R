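test_that("apply_frameshift performs the REF->ALT edit at the CDS offset", {
  v <- tibble::tibble(chrom = "chr1", pos = 7L, ref = "AA", alt = "A",
                      transcript_id = "T1", cds_offset = 6L, strand = "+")
  out <- apply_frameshift("ATGGCAAAGGGTTGA", v)
  expect_equal(out, "ATGGCAAGGGTTGA")

  ins <- tibble::tibble(chrom = "chr1", pos = 6L, ref = "A", alt = "AT",
                        transcript_id = "T1", cds_offset = 5L, strand = "+")
  out2 <- apply_frameshift("ATGGCAAAGGGTTGA", ins)
  expect_equal(nchar(out2), 16L)
  expect_equal(out2, "ATGGCATAAGGGTTGA")

  bad <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "CC", alt = "C",
                        transcript_id = "T1", cds_offset = 0L, strand = "+")
  expect_error(apply_frameshift("ATGGCAAAGGGTTGA", bad), "not found")
})

test_that("mutant_protein splits prefix and shifted tail at the edited codon", {
  v <- tibble::tibble(cds_offset = 6L)
  # deletion mutant of ATG GCA AAG GGT ... with downstream appended
  p <- mutant_protein("ATGGCAAGGGTTTAACCA", v)
  expect_equal(p$prefix, "MA")
  expect_equal(p$tail, "RV")
  expect_false(grepl("\\*", p$full_seq))
  expect_false(p$no_stop_found)

  # immediate stop in the shifted frame -> empty tail
  p2 <- mutant_protein("ATGTAAGCACCA", tibble::tibble(cds_offset = 3L))
  expect_equal(p2$tail, "")
  expect_equal(p2$full_seq, p2$prefix)
})

test_that("in-frame indels are rejected at variant validation", {
  fx <- cached_fixture()
  v <- tibble::tibble(chrom = "chr1", pos = 1L,
                      ref = substr(fx$ref$chromosomes[["chr1"]], 1L, 4L),
                      alt = substr(fx$ref$chromosomes[["chr1"]], 1L, 1L),
                      transcript_id = fx$genes$transcript_id[1])
  expect_error(frameshift_variants(fx$ref, v), "not frameshifting")
})

test_that("REF alleles that do not match the genome are a hard error", {
  fx <- cached_fixture()
  vars <- read_frameshift_vcf(fx$paths$vcf)
  vars$ref[1] <- "QQ"
  expect_error(frameshift_variants(fx$ref, vars), "REF mismatch")
})

test_that("fixture variants build mutants whose prefix matches the canonical protein", {
  fx <- cached_fixture()
  vars <- frameshift_variants(fx$ref, read_frameshift_vcf(fx$paths$vcf))
  mutants <- build_mutant_proteins(fx$ref, vars)
  expect_gt(nrow(mutants), 0L)
  for (i in seq_len(nrow(mutants))) {
    m <- mutants[i, ]
    g <- fx$genes$gene_id[fx$genes$transcript_id == m$transcript_id]
    prot <- fx$proteome[[paste0("PROT", substr(g, 5L, 7L))]]
    expect_equal(m$prefix, substr(prot, 1L, nchar(m$prefix)))
    expect_gt(nchar(m$tail), 0L)
  }
})

test_that("a +1 insertion tail equals the original sequence translated one base later", {
  # hand case: insertion of T after codon 2 shifts everything downstream
  cds <- "ATGGCAAAGGGTCCTGAGCACTAA"
  v <- tibble::tibble(chrom = "c", pos = 7L, ref = "A", alt = "AT",
                      transcript_id = "T1", cds_offset = 6L, strand = "+")
  mut <- apply_frameshift(cds, v)
  p <- mutant_protein(mut, v)
  # after the edited codon, the tail reads the ORIGINAL sequence one base
  # earlier than the old codon grid (the inserted base consumed one slot)
  k <- 2L  # edited codon index
  shifted <- translate_frame(substr(cds, 3L * (k + 1L), nchar(cds)), 0L)
  shifted_clean <- sub("\\*.*$", "", shifted)
  expect_equal(substr(p$tail, 2L, nchar(p$tail)), shifted_clean)
})

test_that("matches must overlap the novel tail", {
  mutants <- tibble::tibble(
    id = "FS1", transcript_id = "T1", chrom = "c", pos = 1L, ref = "A",
    alt = "AT", prefix = "MAGHKW", tail = "RRPLVYE",
    full_seq = "MAGHKWRRPLVYE", no_stop_found = FALSE)
  # entirely within the prefix: not frameshift evidence
  expect_equal(nrow(match_frameshift("MAGHK", mutants)), 0L)
  # entirely within the tail
  h1 <- match_frameshift("RRPLV", mutants)
  expect_equal(nrow(h1), 1L)
  expect_false(h1$spans_junction)
  # spanning the junction
  h2 <- match_frameshift("HKWRRP", mutants)
  expect_equal(nrow(h2), 1L)
  expect_true(h2$spans_junction)
  # I/L distinguished: L->I variant of a tail peptide does not match
  expect_equal(nrow(match_frameshift("RRPIV", mutants)), 0L)
})

test_that("planted fixture tail peptides are recovered and every hit is tail-anchored", {
  fx <- cached_fixture()
  vars <- frameshift_variants(fx$ref, read_frameshift_vcf(fx$paths$vcf))
  mutants <- build_mutant_proteins(fx$ref, vars)
  hits <- match_frameshift(read_peptides(fx$paths$peptides), mutants)
  planted <- fx$truth$sequence[fx$truth$region == "frameshift_tail"]
  expect_true(all(planted %in% hits$sequence))
  # junction-spanning plants are flagged as such
  ph <- hits[hits$sequence %in% planted, ]
  expect_true(all(ph$spans_junction))
  # every reported hit genuinely overlaps the novel tail
  for (i in seq_len(nrow(hits))) {
    m <- mutants[mutants$id == hits$id[i], ]
    expect_gt(hits$offset[i] + nchar(hits$sequence[i]), nchar(m$prefix))
  }
})

test_that("minus-strand variants map genomic positions into spliced CDS offsets", {
  # minus-strand gene: sense CDS ATG AAA CCC GGG TTT TAG over two exons
  sense_cds <- "ATGAAACCCGGGTTT"
  utr3 <- "TAGAAAAAA"
  sense <- paste0(sense_cds, utr3)                  # single exon CDS + 3'UTR
  genomic <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
  chrom <- paste0(strrep("G", 40L), genomic, strrep("G", 40L))
  gene_start <- 40L; len <- nchar(sense)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "-",
                          start = gene_start, end = gene_start + len)
  exons <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                          start = gene_start, end = gene_start + len)
  cds <- tibble::tibble(transcript_id = "T1",
                        start = gene_start + nchar(utr3),
                        end = gene_start + len)
  ref <- ref_from_tables(c(chr1 = chrom), genes, exons, cds)

  # delete the sense base at CDS offset 7 (the second C of AAACCC):
  # in genomic plus coordinates the REF covers the revcomp pair
  # sense offsets 6..7 ("CC") -> genomic [gene_start+len-8, gene_start+len-6)
  g_lo <- gene_start + len - 8L
  ref_allele <- substr(chrom, g_lo + 1L, g_lo + 2L)
  v <- tibble::tibble(chrom = "chr1", pos = g_lo + 1L,
                      ref = ref_allele,
                      alt = substr(ref_allele, 1L, 1L),
                      transcript_id = "T1")
  vv <- frameshift_variants(ref, v)
  expect_equal(vv$strand, "-")
  expect_equal(vv$cds_offset, 6L)  # transcription-direction first REF base
  mut <- build_mutant_proteins(ref, vv)
  expect_equal(mut$prefix, "MK")   # codons fully 5' of the edited codon
  expect_gt(nchar(mut$tail), 0L)
})
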