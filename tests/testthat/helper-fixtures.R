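# Shared fixtures and independent oracles for the test suite.

# Build a reference_model directly from tables, bypassing file IO, for
# small hand-constructed test cases. Coordinates are 0-based half-open.
ref_from_tables <- function(chromosomes, genes, exons, cds = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dir, "g.fa")
  writeLines(unlist(purrr::map2(names(chromosomes), chromosomes,
                                ~ c(paste0(">", .x), .y))), fa)
  gtf <- file.path(dir, "a.gtf")
  lines <- character()
  attr_of <- function(g, tx = NULL, biotype = "protein_coding") {
    a <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                 g, g, biotype)
    if (!is.null(tx)) a <- paste0(a, sprintf(' transcript_id "%s";', tx))
    a
  }
  row <- function(chrom, feat, start, end, strand, attrs) {
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start + 1L, end, strand, attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bt <- if ("biotype" %in% names(genes)) g$biotype else "protein_coding"
    lines <- c(lines, row(g$chrom, "gene", g$start, g$end, g$strand,
                          attr_of(g$gene_id, biotype = bt)))
  }
  txs <- unique(exons$transcript_id)
  for (tx in txs) {
    ex <- exons[exons$transcript_id == tx, ]
    g <- genes[genes$gene_id == ex$gene_id[1], ]
    lines <- c(lines, row(g$chrom, "transcript", min(ex$start), max(ex$end),
                          g$strand, attr_of(g$gene_id, tx)))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, row(g$chrom, "exon", ex$start[j], ex$end[j],
                            g$strand, attr_of(g$gene_id, tx)))
    }
    if (!is.null(cds)) {
      cc <- cds[cds$transcript_id == tx, ]
      for (j in seq_len(nrow(cc))) {
        lines <- c(lines, row(g$chrom, "CDS", cc$start[j], cc$end[j],
                              g$strand, attr_of(g$gene_id, tx)))
      }
    }
  }
  writeLines(lines, gtf)
  load_reference(fa, gtf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoised full-size fixture shared across test files (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 42L, n_genes = 20L) {
  key <- sprintf("fx_%d_%d", seed, n_genes)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), sprintf("ncmapr_fixture_%d_%d", seed, n_genes))
    fx <- make_fixture(fixture_spec(seed = seed, n_genes = n_genes), dir = dir)
    fx$ref <- load_reference(fx$paths$genome, fx$paths$gtf)
    fx$threeft <- build_3ft(fx$ref)
    fx$proteome <- read_proteome_fasta(fx$paths$proteome)
    .fixture_cache[[key]] <- fx
  }
  .fixture_cache[[key]]
}

cached_classification <- function(seed = 42L, n_genes = 20L) {
  key <- sprintf("cl_%d_%d", seed, n_genes)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(seed, n_genes)
    peps <- read_peptides(fx$paths$peptides)
    .fixture_cache[[key]] <- classify_peptides(peps, fx$proteome, fx$threeft)
  }
  .fixture_cache[[key]]
}

# --- independent oracles ----------------------------------------------------

# Brute-force minimum mismatch profile: plain nested loops over every
# window, no vectorisation shared with the implementation.
oracle_min_distance <- function(peptide, proteome) {
  k <- nchar(peptide)
  pv <- strsplit(peptide, "")[[1]]
  best <- list(hard = k, li = 0L, total = k)
  found <- FALSE
  for (prot in proteome) {
    n <- nchar(prot)
    if (n < k) next
    sv <- strsplit(prot, "")[[1]]
    for (off in 0:(n - k)) {
      hard <- 0L; li <- 0L
      for (j in 1:k) {
        a <- pv[j]; b <- sv[off + j]
        if (a != b) {
          if ((a == "I" && b == "L") || (a == "L" && b == "I")) {
            li <- li + 1L
          } else {
            hard <- hard + 1L
          }
        }
      }
      tot <- hard + li
      if (!found || tot < best$total ||
          (tot == best$total && hard < best$hard)) {
        best <- list(hard = hard, li = li, total = tot)
        found <- TRUE
      }
    }
  }
  best
}

# Splice-and-translate oracle for the intron-retention frame test: build
# the retained-intron transcript in transcription order, locate the
# peptide's 5' base in transcript coordinates, and test whether it falls on
# a codon boundary of the translation that starts at the first exon's 5'
# end. Independent of the implementation's inframe-coordinate bookkeeping.
#
# exons: tibble with start/end (genomic ascending); upto: 1-based index of
# the upstream exon in transcription order; p5: genomic position of the
# peptide's transcription-direction first base (must lie in that intron).
oracle_ir_inframe <- function(exons, strand, upto, p5) {
  exons <- exons[order(exons$start), ]
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  exonic_before <- 0L
  for (k in seq_len(upto)) {
    i <- ord[k]
    exonic_before <- exonic_before + (exons$end[i] - exons$start[i])
  }
  i <- ord[upto]; j <- ord[upto + 1L]
  if (strand == "+") {
    intron <- c(exons$end[i], exons$start[j])
    stopifnot(p5 >= intron[1], p5 < intron[2])
    t <- exonic_before + (p5 - intron[1])
  } else {
    intron <- c(exons$end[j], exons$start[i])
    stopifnot(p5 >= intron[1], p5 < intron[2])
    t <- exonic_before + (intron[2] - 1L - p5)
  }
  t %% 3L == 0L
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_aa <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}
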