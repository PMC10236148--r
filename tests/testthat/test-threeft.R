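# nucleotide encoding used to hand-build genes around known translations
encode_aa_nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  paste(vapply(strsplit(aa, "")[[1]], function(a) by_aa[[a]][1], ""),
        collapse = "")
}

single_gene_ref <- function(sense, strand = "+", pad = 30L) {
  chrom <- if (strand == "+") {
    paste0(strrep("T", pad), sense, strrep("T", pad))
  } else {
    paste0(strrep("T", pad),
           as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense))),
           strrep("T", pad))
  }
  ref_from_tables(
    c(chr1 = chrom),
    tibble::tibble(gene_id = "G1", chrom = "chr1", strand = strand,
                   start = pad, end = pad + nchar(sense)),
    tibble::tibble(transcript_id = "T1", gene_id = "G1",
                   start = pad, end = pad + nchar(sense)))
}

test_that("build_3ft splits frame translations at stops and drops short segments", {
  sense <- encode_aa_nt("MKLLT*AFAPFPTQF")
  ref <- single_gene_ref(sense)
  segs <- build_3ft(ref, min_len = 7L)
  frame0 <- segs[segs$frame == 0L, ]
  expect_equal(nrow(frame0), 1L)  # "MKLLT" (5 aa) dropped, 9-mer kept
  expect_equal(frame0$aa_seq, "AFAPFPTQF")
  expect_equal(frame0$anchor, 30L + 3L * 6L)

  # with min_len = 1 both frame-0 segments survive
  all_segs <- build_3ft(ref, min_len = 1L)
  f0 <- all_segs[all_segs$frame == 0L, ]
  expect_setequal(f0$aa_seq, c("MKLLT", "AFAPFPTQF"))
})

test_that("a gene with no stop-free stretch >= min_len yields no segments", {
  sense <- encode_aa_nt("MK*LT*")  # too short for 7 clean codons in any frame
  ref <- single_gene_ref(sense)
  expect_equal(nrow(build_3ft(ref, min_len = 7L)), 0L)
})

test_that("raising min_len never increases the segment count", {
  fx <- cached_fixture()
  n7 <- nrow(fx$threeft)
  n14 <- nrow(build_3ft(fx$ref, min_len = 14L))
  expect_lte(n14, n7)
})

test_that("every emitted segment re-translates from its genomic slice", {
  fx <- cached_fixture()
  segs <- fx$threeft
  set.seed(11)
  idx <- sample.int(nrow(segs), 100L)
  for (i in idx) {
    seg <- segs[i, ]
    iv <- segment_to_genomic(seg, 0L, nchar(seg$aa_seq))
    slice <- substr(fx$ref$chromosomes[[seg$chrom]], iv$start + 1L, iv$end)
    if (seg$strand == "-") {
      slice <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice)))
    }
    expect_equal(translate_frame(slice, 0L), seg$aa_seq)
  }
})

test_that("segments concatenated with their separators reconstruct the frame translation", {
  fx <- cached_fixture()
  ref <- fx$ref
  g <- ref$genes[ref$genes$strand == "+" &
                   ref$genes$biotype == "protein_coding", ][1, ]
  segs <- build_3ft(ref, min_len = 1L)
  segs <- segs[segs$gene_id == g$gene_id & segs$frame == 0L, ]
  full <- translate_frame(premrna_sequence(ref, g$gene_id), 0L)
  expect_false(any(grepl("[*X]", segs$aa_seq)))
  for (i in seq_len(nrow(segs))) {
    aa_start <- (segs$anchor[i] - g$start) / 3L  # frame 0, plus strand
    expect_equal(substr(full, aa_start + 1L, aa_start + nchar(segs$aa_seq[i])),
                 segs$aa_seq[i])
  }
  # conservation: clean residues in segments equal clean residues in full
  expect_equal(sum(nchar(segs$aa_seq)),
               nchar(gsub("[*X]", "", full)))
})

test_that("segment_to_genomic follows its closed-form definition", {
  seg <- tibble::tibble(chrom = "chr1", strand = "+", anchor = 300L,
                        aa_seq = strrep("A", 20L))
  iv <- segment_to_genomic(seg, 0L, 9L)
  expect_equal(c(iv$start, iv$end), c(300L, 327L))
  iv2 <- segment_to_genomic(seg, 2L, 3L)
  expect_equal(c(iv2$start, iv2$end), c(306L, 315L))
  expect_equal(iv2$end - iv2$start, 9L)
  expect_error(segment_to_genomic(seg, 15L, 9L), "out of range")
})

test_that("minus-strand windows round-trip through genomic coordinates", {
  sense <- encode_aa_nt("MAWFHKDNPQRSTVYE")
  ref <- single_gene_ref(sense, strand = "-")
  segs <- build_3ft(ref, min_len = 7L)
  seg <- segs[segs$frame == 0L, ][1, ]
  for (aa_start in c(0L, 3L, 5L)) {
    iv <- segment_to_genomic(seg, aa_start, 7L)
    slice <- substr(ref$chromosomes[["chr1"]], iv$start + 1L, iv$end)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice)))
    expect_equal(translate_frame(rc, 0L),
                 substr(seg$aa_seq, aa_start + 1L, aa_start + 7L))
  }
})

test_that("3FT headers follow the fixed grammar and round-trip", {
  seg <- tibble::tibble(gene_id = "G1", chrom = "chr1", strand = "+",
                        frame = 2L, anchor = 1045L, segment_index = 3L,
                        aa_seq = "AFAPFPTQF", length = 9L)
  path <- withr::local_tempfile(fileext = ".fa")
  write_3ft_fasta(seg, path)
  expect_equal(readLines(path)[1], ">3FT|G1|chr1|+|2|1045|3")

  set.seed(21)
  for (i in 1:25) {
    seg_i <- tibble::tibble(
      gene_id = sprintf("G%d", sample.int(1e6, 1L)), chrom = "chr2",
      strand = sample(c("+", "-"), 1L), frame = sample(0:2, 1L),
      anchor = sample.int(1e8, 1L), segment_index = sample.int(100, 1L),
      aa_seq = random_aa(9L), length = 9L)
    parsed <- parse_3ft_header(sprintf(
      "3FT|%s|%s|%s|%d|%d|%d", seg_i$gene_id, seg_i$chrom, seg_i$strand,
      seg_i$frame, seg_i$anchor, seg_i$segment_index))
    expect_equal(parsed$gene_id, seg_i$gene_id)
    expect_equal(parsed$anchor, seg_i$anchor)
    expect_equal(parsed$strand, seg_i$strand)
    expect_equal(parsed$frame, seg_i$frame)
  }
  expect_error(parse_3ft_header("3FT|G1|chr1|+|2"), "malformed")
  expect_error(parse_3ft_header("XX|G1|chr1|+|2|10|1"), "malformed")
})

test_that("a written 3FT FASTA reads back identically", {
  fx <- cached_fixture()
  path <- withr::local_tempfile(fileext = ".fa")
  write_3ft_fasta(fx$threeft, path)
  back <- read_3ft_fasta(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(fx$threeft))
})
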