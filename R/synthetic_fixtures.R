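#' Specification for a synthetic fixture
#'
#' Describes a deterministic toy dataset with planted ground truth:
#' multi-exon protein-coding genes on both strands carrying planted
#' canonical peptides, noncanonical peptides in 5'UTRs (with an upstream
#' near-cognate start codon), introns (both in and out of frame with the
#' upstream exon), 3'UTRs and alternative exonic frames, frameshift
#' variants with tail peptides, and GTEx/HPA-style expression and
#' protein-evidence tables straddling the 1 TPM selectivity cutoff. The
#' same seed always regenerates byte-identical outputs.
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_genes Number of protein-coding genes (at most 20).
#' @param canonical_per_gene Planted canonical peptides per gene.
#' @param tissues Tissue names for the expression table (must include
#'   `"testis"`).
#' @param samples_per_tissue Samples per tissue in the expression table.
#' @param protein_denominator Healthy-tissue denominator for the
#'   protein-evidence table.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_genes = 20L, canonical_per_gene = 5L,
                         tissues = c("adipose", "brain", "colon", "liver",
                                     "lung", "muscle", "skin", "testis"),
                         samples_per_tissue = 10L,
                         protein_denominator = 56L) {
  stopifnot(n_genes >= 2L, n_genes <= 20L, "testis" %in% tissues)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 canonical_per_gene = as.integer(canonical_per_gene),
                 tissues = tissues,
                 samples_per_tissue = as.integer(samples_per_tissue),
                 protein_denominator = as.integer(protein_denominator)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")
AA20 <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))

rand_nt <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

genetic_code_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# random nucleotide encoding of an amino-acid string
encode_peptide_nt <- function(aa) {
  by_aa <- genetic_code_by_aa()
  paste(purrr::map_chr(strsplit(aa, "")[[1]], function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }), collapse = "")
}

sense_codons <- function() setdiff(names(Biostrings::GENETIC_CODE),
                                   STOP_CODONS)

rand_cds_codons <- function(n) {
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}

# codons safe inside an upstream-scan corridor: no stops, no near-cognate
# starts, so the scan finds exactly the planted start codon
scan_safe_codons <- function(n) {
  safe <- setdiff(sense_codons(), NEAR_COGNATE_STARTS)
  paste(sample(safe, n, replace = TRUE), collapse = "")
}

# replace [at, at + nchar(piece)) of s (0-based) with piece
splice_in <- function(s, at, piece) {
  stopifnot(at >= 0L, at + nchar(piece) <= nchar(s))
  paste0(substr(s, 1L, at), piece, substr(s, at + nchar(piece) + 1L, nchar(s)))
}

# sense-space [s, e) -> genomic [start, end) for a gene at gene_start with
# sense length len
sense_to_genomic <- function(s, e, gene_start, len, strand) {
  if (strand == "+") {
    c(gene_start + s, gene_start + e)
  } else {
    c(gene_start + len - e, gene_start + len - s)
  }
}

# --- single-gene skeleton in sense space ------------------------------------

build_gene_skeleton <- function(idx, strand, canonical_per_gene) {
  # 5'UTR exon with the upstream-ORF corridor; the planted block is
  # [stop][near-cognate start][safe filler][peptide], all in one frame
  pre1 <- rand_nt(sample(15:30, 1L))
  start_codon <- sample(NEAR_COGNATE_STARTS, 1L)
  filler_n <- sample(3:6, 1L)
  pep5 <- rand_aa(9L)
  block <- paste0(sample(STOP_CODONS, 1L), start_codon,
                  scan_safe_codons(filler_n), encode_peptide_nt(pep5))
  post1 <- rand_nt(sample(10:20, 1L))
  exon1 <- paste0(pre1, block, post1)
  pep5_at <- nchar(pre1) + 6L + 3L * filler_n  # sense offset of the peptide

  # CDS: ATG + random stop-free codons, split across exons 2 and 3 at an
  # arbitrary (often non-codon) boundary to exercise frame propagation
  n_codons <- sample(40:60, 1L)
  cds <- paste0("ATG", rand_cds_codons(n_codons - 1L))
  cut <- sample(seq(45L, nchar(cds) - 30L), 1L)

  intron1 <- rand_nt(sample(70:110, 1L))
  intron2 <- rand_nt(sample(70:110, 1L))
  stop_codon <- sample(STOP_CODONS, 1L)
  utr3_pre <- rand_nt(sample(15:30, 1L))
  pep3 <- rand_aa(9L)
  utr3_post <- rand_nt(sample(15:30, 1L))

  list(idx = idx, strand = strand,
       exon1 = exon1, intron1 = intron1,
       cds = cds, cut = cut, intron2 = intron2,
       stop_codon = stop_codon, utr3_pre = utr3_pre, utr3_post = utr3_post,
       pep5 = pep5, pep5_at = pep5_at, start_codon = start_codon,
       pep3 = pep3, canonical_per_gene = canonical_per_gene)
}

# assemble the sense sequence and the sense-space coordinate table
assemble_gene <- function(g) {
  exon2 <- substr(g$cds, 1L, g$cut)
  exon3_cds <- substr(g$cds, g$cut + 1L, nchar(g$cds))
  utr3 <- paste0(g$stop_codon, g$utr3_pre, encode_peptide_nt(g$pep3),
                 g$utr3_post)
  pep3_at_in_utr3 <- 3L + nchar(g$utr3_pre)

  e1 <- nchar(g$exon1)
  i1 <- nchar(g$intron1)
  e2 <- nchar(exon2)
  i2 <- nchar(g$intron2)
  e3 <- nchar(exon3_cds) + nchar(utr3)

  sense <- paste0(g$exon1, g$intron1, exon2, g$intron2, exon3_cds, utr3)
  coords <- list(
    exon1 = c(0L, e1),
    intron1 = c(e1, e1 + i1),
    exon2 = c(e1 + i1, e1 + i1 + e2),
    intron2 = c(e1 + i1 + e2, e1 + i1 + e2 + i2),
    exon3 = c(e1 + i1 + e2 + i2, e1 + i1 + e2 + i2 + e3),
    cds_a = c(e1 + i1, e1 + i1 + e2),
    cds_b = c(e1 + i1 + e2 + i2, e1 + i1 + e2 + i2 + nchar(exon3_cds)),
    pep5 = c(g$pep5_at, g$pep5_at + 27L),
    pep3_at = e1 + i1 + e2 + i2 + nchar(exon3_cds) + pep3_at_in_utr3
  )
  list(sense = sense, coords = coords)
}

# sense-space positions (mod 3) that are in-frame with the upstream exons
# when the intron beginning at `intron_start` is retained
retained_grid_anchor <- function(intron_start, exonic_before) {
  intron_start + (3L - exonic_before %% 3L) %% 3L
}

# draw a peptide, encode and embed it at a sense position chosen so that
# (pos - anchor) %% 3 == phase; returns the updated sense string + plant
embed_peptide <- function(sense, region, exonic_anchor, phase, margin = 6L) {
  lo <- region[1] + margin
  hi <- region[2] - margin - 27L
  stopifnot(hi >= lo)
  pos <- sample(seq(lo, hi), 1L)
  pos <- pos + (phase - (pos - exonic_anchor)) %% 3L
  if (pos + 27L + margin > region[2]) pos <- pos - 3L
  stopifnot(pos >= region[1] + 3L, pos + 27L <= region[2] - 3L)
  pep <- rand_aa(9L)
  list(sense = splice_in(sense, pos, encode_peptide_nt(pep)),
       pep = pep, at = pos)
}

# occurrences of a peptide across the three frame translations of all
# gene sense sequences (generation-time uniqueness check)
count_3ft_occurrences <- function(pep, senses) {
  sum(purrr::map_int(senses, function(s) {
    sum(purrr::map_int(0:2, function(f) {
      stringr::str_count(translate_frame(s, f), stringr::fixed(pep))
    }))
  }))
}

# memoised three-frame translations of the gene sense sequences; recomputes
# a gene's frames only when its sense sequence has changed since last use
make_trans_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$sense <- character()
  cache$trans <- list()
  function(senses) {
    n <- length(senses)
    if (length(cache$sense) != n) {
      cache$sense <- rep("", n)
      cache$trans <- vector("list", n)
    }
    for (i in seq_len(n)) {
      if (!identical(cache$sense[i], senses[i])) {
        cache$trans[[i]] <- purrr::map_chr(0:2, ~ translate_frame(senses[i], .x))
        cache$sense[i] <- senses[i]
      }
    }
    cache$trans
  }
}

count_occurrences_cached <- function(pep, senses, get_trans) {
  sum(purrr::map_int(get_trans(senses),
                     ~ sum(stringr::str_count(.x, stringr::fixed(pep)))))
}

#' Generate a synthetic reference with planted ground truth
#'
#' Writes a genome FASTA, an ENSEMBL-style GTF, a proteome FASTA, a peptide
#' list, a frameshift VCF and a truth table into `dir`. Every planted
#' peptide is verified at generation time: noncanonical peptides are
#' re-drawn until they are at least 3 mismatches (Hamming, I/L counted
#' separately) from every window of the final proteome and occur exactly
#' once in the three-frame translation space; in-frame intronic plants
#' satisfy the retained-intron codon-grid condition by construction.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `paths` (named file paths), `truth` (tibble of
#'   planted peptides and their expected annotations), `genes` (gene design
#'   tibble) and `spec`.
#' @export
make_reference <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, make_reference_impl(spec, dir))
}

make_reference_impl <- function(spec, dir) {
  n <- spec$n_genes
  strands <- rep(c("+", "-"), length.out = n)
  skel <- purrr::map(seq_len(n), function(i) {
    build_gene_skeleton(i, strands[i], spec$canonical_per_gene)
  })
  built <- purrr::map(skel, assemble_gene)
  senses <- purrr::map_chr(built, "sense")
  coords <- purrr::map(built, "coords")
  get_trans <- make_trans_cache()

  protein_of <- function(i) {
    co <- coords[[i]]
    cds_nt <- paste0(substr(senses[i], co$cds_a[1] + 1L, co$cds_a[2]),
                     substr(senses[i], co$cds_b[1] + 1L, co$cds_b[2]))
    translate_frame(cds_nt, 0L)
  }

  # --- exonic alternative-frame plants (perturb the proteome) -------------
  alt_plants <- vector("list", n)
  for (i in seq_len(n)) {
    co <- coords[[i]]
    cds_grid <- co$cds_a[1]  # CDS codon starts are congruent to this mod 3
    repeat {
      emb <- embed_peptide(senses[i], co$cds_a, cds_grid,
                           phase = sample(1:2, 1L))
      # keep only embeddings that leave the canonical frame stop-free
      test_sense <- emb$sense
      co_cds <- paste0(substr(test_sense, co$cds_a[1] + 1L, co$cds_a[2]),
                       substr(test_sense, co$cds_b[1] + 1L, co$cds_b[2]))
      prot <- translate_frame(co_cds, 0L)
      if (!stringr::str_detect(prot, "\\*")) {
        senses[i] <- test_sense
        alt_plants[[i]] <- list(pep = emb$pep, at = emb$at)
        break
      }
    }
  }
  proteins <- purrr::map_chr(seq_len(n), protein_of)
  names(proteins) <- sprintf("PROT%03d", seq_len(n))

  # redraw any alt-frame plant that landed too close to the proteome
  repeat {
    bad <- which(purrr::map_lgl(seq_len(n), function(i) {
      d <- min_proteome_distance(alt_plants[[i]]$pep, proteins)
      d$hard + d$li < 3L ||
        count_occurrences_cached(alt_plants[[i]]$pep, senses, get_trans) != 1L
    }))
    if (length(bad) == 0L) break
    for (i in bad) {
      co <- coords[[i]]
      old <- alt_plants[[i]]
      pep <- rand_aa(9L)
      senses[i] <- splice_in(senses[i], old$at, encode_peptide_nt(pep))
      alt_plants[[i]]$pep <- pep
      proteins[i] <- protein_of(i)
    }
  }

  # --- non-exonic noncanonical plants (proteome now frozen) ---------------
  plant_verified <- function(i, region, anchor, phase) {
    repeat {
      emb <- embed_peptide(senses[i], region, anchor, phase)
      senses_try <- senses; senses_try[i] <- emb$sense
      d <- min_proteome_distance(emb$pep, proteins)
      if (d$hard + d$li >= 3L &&
          count_occurrences_cached(emb$pep, senses_try, get_trans) == 1L) {
        senses[i] <<- emb$sense
        return(emb)
      }
    }
  }

  plants <- purrr::map(seq_len(n), function(i) {
    co <- coords[[i]]
    len_e1 <- co$exon1[2] - co$exon1[1]
    len_e2 <- co$exon2[2] - co$exon2[1]
    grid1 <- retained_grid_anchor(co$intron1[1], len_e1)
    grid2 <- retained_grid_anchor(co$intron2[1], len_e1 + len_e2)
    list(
      intron_in = plant_verified(i, co$intron1, grid1, phase = 0L),
      intron_out = plant_verified(i, co$intron2, grid2,
                                  phase = sample(1:2, 1L))
    )
  })

  # the 5'UTR and 3'UTR peptides were embedded at skeleton time; verify and
  # redraw in place if needed
  for (i in seq_len(n)) {
    co <- coords[[i]]
    for (which_pep in c("pep5", "pep3")) {
      at <- if (which_pep == "pep5") co$pep5[1] else co$pep3_at
      repeat {
        pep <- if (which_pep == "pep5") skel[[i]]$pep5 else skel[[i]]$pep3
        d <- min_proteome_distance(pep, proteins)
        if (d$hard + d$li >= 3L &&
            count_occurrences_cached(pep, senses, get_trans) == 1L) {
          break
        }
        pep <- rand_aa(9L)
        senses[i] <- splice_in(senses[i], at, encode_peptide_nt(pep))
        if (which_pep == "pep5") skel[[i]]$pep5 <- pep else skel[[i]]$pep3 <- pep
      }
    }
  }

  # --- canonical plants (globally unique windows of the final proteins) ---
  used <- character()
  canon <- purrr::map(seq_len(n), function(i) {
    prot <- proteins[[i]]
    out <- character()
    while (length(out) < spec$canonical_per_gene) {
      len <- sample(9:11, 1L)
      at <- sample.int(nchar(prot) - len + 1L, 1L)
      pep <- substr(prot, at, at + len - 1L)
      if (!pep %in% used) {
        out <- c(out, pep)
        used <<- c(used, pep)
      }
    }
    out
  })

  # --- genome assembly ----------------------------------------------------
  n_chroms <- 2L
  chrom_of <- rep(seq_len(n_chroms), length.out = n)
  chrom_seqs <- stats::setNames(rep("", n_chroms),
                                paste0("chr", seq_len(n_chroms)))
  gene_start <- integer(n)
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    spacer <- rand_nt(sample(150:250, 1L))
    chrom_seqs[ch] <- paste0(chrom_seqs[ch], spacer)
    gene_start[i] <- nchar(chrom_seqs[ch])
    slice <- if (strands[i] == "-") reverse_complement(senses[i]) else senses[i]
    chrom_seqs[ch] <- paste0(chrom_seqs[ch], slice)
  }
  chrom_seqs <- purrr::map_chr(chrom_seqs, ~ paste0(.x, rand_nt(200L)))

  # one noncoding gene exercising the biotype filter
  nc_start <- nchar(chrom_seqs[1]) ; nc_len <- 300L
  chrom_seqs[1] <- paste0(chrom_seqs[1], rand_nt(nc_len), rand_nt(100L))

  # --- GTF + truth --------------------------------------------------------
  gtf <- list(); truth <- list()
  add_gtf <- function(chrom, feat, start0, end0, strand, gene, tx = NULL,
                      biotype = "protein_coding") {
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     gene, gene, biotype)
    if (!is.null(tx)) {
      attrs <- paste0(attrs, sprintf(' transcript_id "%s";', tx))
    }
    gtf[[length(gtf) + 1L]] <<- sprintf(
      "%s\tfixture\t%s\t%d\t%d\t.\t%s\t.\t%s",
      chrom, feat, start0 + 1L, end0, strand, attrs)
  }
  pep_interval <- function(i, at) {
    g <- sense_to_genomic(at, at + 27L, gene_start[i],
                          nchar(senses[i]), strands[i])
    g
  }
  gene_ids <- sprintf("GENE%03d", seq_len(n))
  tx_ids <- sprintf("TX%03d", seq_len(n))

  designs <- rep(c("low_noprot", "low_prot", "high", "testis_only"),
                 length.out = n)
  sel_label <- c(low_noprot = "cancer_selective",
                 low_prot = "protein_expressed",
                 high = "expressed_above_cutoff",
                 testis_only = "cancer_selective")

  add_truth <- function(...) truth[[length(truth) + 1L]] <<- tibble::tibble(...)

  for (i in seq_len(n)) {
    co <- coords[[i]]
    ch <- paste0("chr", chrom_of[i])
    len <- nchar(senses[i])
    gs <- gene_start[i]
    st <- strands[i]
    span <- sense_to_genomic(0L, len, gs, len, st)
    add_gtf(ch, "gene", span[1], span[2], st, gene_ids[i])
    add_gtf(ch, "transcript", span[1], span[2], st, gene_ids[i], tx_ids[i])
    for (r in c("exon1", "exon2", "exon3")) {
      g <- sense_to_genomic(co[[r]][1], co[[r]][2], gs, len, st)
      add_gtf(ch, "exon", g[1], g[2], st, gene_ids[i], tx_ids[i])
    }
    for (r in c("cds_a", "cds_b")) {
      g <- sense_to_genomic(co[[r]][1], co[[r]][2], gs, len, st)
      add_gtf(ch, "CDS", g[1], g[2], st, gene_ids[i], tx_ids[i])
    }

    panel_flag <- (i %% 2L == 0L)  # one panel peptide per even gene
    base_label <- sel_label[[designs[i]]]
    nc_row <- function(pep, at, region, label, ir, codon, in_panel) {
      g <- pep_interval(i, at)
      add_truth(sequence = pep, gene_id = gene_ids[i], strand = st,
                category = "noncanonical", region = region,
                feature_label = label, ir_in_frame = ir,
                upstream_codon = codon, start = g[1], end = g[2],
                in_panel = in_panel,
                selectivity = if (in_panel) "non_cancer_selective_ms"
                              else base_label,
                expression_design = designs[i])
    }
    nc_row(skel[[i]]$pep5, co$pep5[1], "five_prime_utr", "five_prime_utr",
           NA, skel[[i]]$start_codon, FALSE)
    nc_row(plants[[i]]$intron_in$pep, plants[[i]]$intron_in$at,
           "intronic_inframe", "intronic", TRUE, NA_character_, panel_flag)
    nc_row(plants[[i]]$intron_out$pep, plants[[i]]$intron_out$at,
           "intronic_outframe", "intronic", FALSE, NA_character_, FALSE)
    nc_row(skel[[i]]$pep3, co$pep3_at, "three_prime_utr", "three_prime_utr",
           NA, NA_character_, FALSE)
    nc_row(alt_plants[[i]]$pep, alt_plants[[i]]$at, "exonic_alt_frame",
           "exonic_alt_frame", NA, NA_character_, FALSE)
    for (pep in canon[[i]]) {
      add_truth(sequence = pep, gene_id = gene_ids[i], strand = st,
                category = "canonical", region = "canonical",
                feature_label = NA_character_, ir_in_frame = NA,
                upstream_codon = NA_character_, start = NA_integer_,
                end = NA_integer_, in_panel = FALSE,
                selectivity = NA_character_,
                expression_design = designs[i])
    }
  }
  add_gtf("chr1", "gene", nc_start, nc_start + nc_len, "+", "GENE_NC1",
          biotype = "lincRNA")
  add_gtf("chr1", "transcript", nc_start, nc_start + nc_len, "+", "GENE_NC1",
          "TX_NC1", biotype = "lincRNA")
  add_gtf("chr1", "exon", nc_start, nc_start + nc_len, "+", "GENE_NC1",
          "TX_NC1", biotype = "lincRNA")

  # --- frameshift variants (plus-strand genes, every other one) -----------
  vcf_rows <- list()
  plus_genes <- which(strands == "+")
  fs_genes <- plus_genes[seq_along(plus_genes) %% 2L == 1L]
  for (i in fs_genes) {
    co <- coords[[i]]
    cds_nt <- paste0(substr(senses[i], co$cds_a[1] + 1L, co$cds_a[2]),
                     substr(senses[i], co$cds_b[1] + 1L, co$cds_b[2]))
    down <- paste0(  # spliced 3'UTR, then genomic continuation (spacer)
      substr(senses[i], co$cds_b[2] + 1L, nchar(senses[i])),
      substr(chrom_seqs[[paste0("chr", chrom_of[i])]],
             gene_start[i] + nchar(senses[i]) + 1L,
             gene_start[i] + nchar(senses[i]) + 200L))
    cds_len <- nchar(cds_nt)
    offsets <- sample(seq(9L, min(co$cds_a[2] - co$cds_a[1], cds_len) - 15L))
    planted <- FALSE
    for (o in offsets) {
      full <- paste0(cds_nt, down)
      mutant <- paste0(substr(full, 1L, o + 1L),
                       substr(full, o + 3L, nchar(full)))  # delete base o+1
      aa <- translate_frame(mutant, 0L)
      edit_codon <- o %/% 3L
      prefix <- substr(aa, 1L, edit_codon)
      rest <- substr(aa, edit_codon + 1L, nchar(aa))
      stop_at <- stringr::str_locate(rest, "\\*")[1, "start"]
      if (is.na(stop_at) || stop_at < 8L) next
      tail <- substr(rest, 1L, stop_at - 1L)
      pep <- substr(paste0(prefix, tail), nchar(prefix) - 2L,
                    nchar(prefix) + 6L)
      d <- min_proteome_distance(pep, proteins)
      if (d$hard + d$li < 3L ||
          count_occurrences_cached(pep, senses, get_trans) != 0L) next
      pos0 <- gene_start[i] + co$cds_a[1] + o  # genomic, 0-based (plus)
      ref_allele <- substr(chrom_seqs[[paste0("chr", chrom_of[i])]],
                           pos0 + 1L, pos0 + 2L)
      vcf_rows[[length(vcf_rows) + 1L]] <- sprintf(
        "%s\t%d\t.\t%s\t%s\t.\t.\tTRANSCRIPT=%s",
        paste0("chr", chrom_of[i]), pos0 + 1L, ref_allele,
        substr(ref_allele, 1L, 1L), tx_ids[i])
      add_truth(sequence = pep, gene_id = gene_ids[i], strand = "+",
                category = "unmapped", region = "frameshift_tail",
                feature_label = NA_character_, ir_in_frame = NA,
                upstream_codon = NA_character_, start = NA_integer_,
                end = NA_integer_, in_panel = FALSE,
                selectivity = NA_character_,
                expression_design = designs[i])
      planted <- TRUE
      break
    }
    if (!planted) abort("could not plant a frameshift tail peptide")
  }

  truth_tbl <- dplyr::bind_rows(truth)
  stopifnot(!anyDuplicated(truth_tbl$sequence))

  # --- write files --------------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    proteome = file.path(dir, "proteome.fa"),
    peptides = file.path(dir, "peptides.tsv"),
    truth = file.path(dir, "truth.tsv"),
    vcf = file.path(dir, "variants.vcf")
  )
  genome_set <- Biostrings::DNAStringSet(chrom_seqs)
  Biostrings::writeXStringSet(genome_set, paths$genome, width = 70L)
  readr::write_lines(unlist(gtf), paths$gtf)
  prot_set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(prot_set, paths$proteome, width = 70L)
  peptides <- truth_tbl %>%
    dplyr::transmute(sequence = .data$sequence,
                     sample_id = sprintf("S%02d", seq_len(nrow(truth_tbl)) %% 4L + 1L),
                     score = round(stats::runif(nrow(truth_tbl), 0.5, 1), 4))
  readr::write_tsv(peptides, paths$peptides)
  readr::write_tsv(truth_tbl, paths$truth)
  readr::write_lines(c("##fileformat=VCFv4.2",
                       "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                       unlist(vcf_rows)), paths$vcf)

  genes_tbl <- tibble::tibble(gene_id = gene_ids, transcript_id = tx_ids,
                              strand = strands,
                              chrom = paste0("chr", chrom_of),
                              expression_design = designs)
  list(paths = paths, truth = truth_tbl, genes = genes_tbl, spec = spec)
}

#' Generate GTEx/HPA-style expression and protein-evidence tables
#'
#' Sample-level TPM values are log-normal draws whose designed per-tissue
#' 90th percentiles straddle the 1 TPM cutoff: `low_*` genes sit far below
#' it in every tissue, `high` genes exceed it in one non-testis tissue, and
#' `testis_only` genes are high in testis alone (and therefore pass the
#' cutoff under the default testis exclusion). Protein-evidence counts are
#' 0 for `*_noprot` and `testis_only` genes and positive for `low_prot` and
#' `high` genes. The designed percentile relations are asserted after
#' drawing.
#'
#' @param spec A [fixture_spec()].
#' @param genes Gene design tibble from [make_reference()].
#' @param dir Output directory.
#' @return A list with `paths` (expression, protein_evidence, panel),
#'   `expression` and `protein_evidence` tibbles.
#' @export
make_expression <- function(spec, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed + 1L, make_expression_impl(spec, genes, dir))
}

make_expression_impl <- function(spec, genes, dir) {
  tissues <- spec$tissues
  m <- spec$samples_per_tissue
  draw <- function(meanlog, sdlog) {
    round(stats::rlnorm(m, meanlog = meanlog, sdlog = sdlog), 4)
  }
  rows <- purrr::pmap(genes, function(gene_id, transcript_id, strand, chrom,
                                      expression_design) {
    high_tissue <- switch(expression_design,
      high = sample(setdiff(tissues, "testis"), 1L),
      testis_only = "testis",
      NA_character_)
    purrr::map(tissues, function(ts) {
      vals <- if (!is.na(high_tissue) && ts == high_tissue) {
        draw(log(12), 0.3)
      } else {
        draw(log(0.05), 0.4)
      }
      tibble::tibble(gene_id = gene_id, tissue = ts,
                     sample_id = sprintf("%s_%02d", ts, seq_len(m)),
                     tpm = vals)
    })
  })
  expression <- dplyr::bind_rows(purrr::list_flatten(rows))

  # assert the designed relation between the 90th percentiles and the cutoff
  q90 <- tissue_percentile(expression, q = 90)
  check <- q90 %>%
    dplyr::left_join(genes[, c("gene_id", "expression_design")], by = "gene_id") %>%
    dplyr::group_by(.data$gene_id, .data$expression_design) %>%
    dplyr::summarise(
      max_non_testis = max(.data$tpm_q[.data$tissue != "testis"]),
      max_testis = max(.data$tpm_q[.data$tissue == "testis"]),
      .groups = "drop")
  stopifnot(
    all(check$max_non_testis[check$expression_design %in%
                               c("low_noprot", "low_prot", "testis_only")] < 1),
    all(check$max_non_testis[check$expression_design == "high"] >= 1),
    all(check$max_testis[check$expression_design == "testis_only"] >= 1)
  )

  denom <- spec$protein_denominator
  protein_evidence <- genes %>%
    dplyr::transmute(
      gene_id = .data$gene_id,
      n_tissues = dplyr::case_when(
        .data$expression_design == "low_prot" ~ sample(1:45, dplyr::n(),
                                                       replace = TRUE),
        .data$expression_design == "high" ~ sample(10:50, dplyr::n(),
                                                   replace = TRUE),
        TRUE ~ 0L
      ),
      denominator = denom
    )

  paths <- list(expression = file.path(dir, "expression.tsv"),
                protein_evidence = file.path(dir, "protein_evidence.tsv"))
  readr::write_tsv(expression, paths$expression)
  readr::write_tsv(protein_evidence, paths$protein_evidence)
  list(paths = paths, expression = expression,
       protein_evidence = protein_evidence)
}

#' Generate a complete fixture (reference + expression + panel)
#'
#' Convenience wrapper running [make_reference()] and [make_expression()]
#' and writing the panel-of-normals peptide list derived from the planted
#' truth.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return A list with `paths`, `truth`, `genes`, `spec`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  ref_out <- make_reference(spec, dir)
  expr_out <- make_expression(spec, ref_out$genes, dir)
  panel <- ref_out$truth$sequence[ref_out$truth$in_panel]
  panel_path <- file.path(dir, "panel.txt")
  readr::write_lines(panel, panel_path)
  list(paths = c(ref_out$paths, expr_out$paths, list(panel = panel_path)),
       truth = ref_out$truth, genes = ref_out$genes, spec = spec)
}
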