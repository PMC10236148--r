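#' Read a minimal VCF of coding indels
#'
#' Parses the CHROM/POS/REF/ALT columns of a plain-text VCF. The affected
#' transcript is taken from a `TRANSCRIPT=` key in the INFO column, or from
#' a sidecar TSV (`chrom`, `pos`, `transcript_id`) when given.
#'
#' @param path VCF path (uncompressed).
#' @param transcript_map Optional sidecar TSV path.
#' @return Tibble (chrom, pos, ref, alt, transcript_id); `pos` is 1-based
#'   as in the VCF.
#' @export
read_frameshift_vcf <- function(path, transcript_map = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!stringr::str_starts(lines, "#") & nchar(lines) > 0L]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          transcript_id = character()))
  }
  fields <- stringr::str_split(lines, "\t")
  tbl <- tibble::tibble(
    chrom = purrr::map_chr(fields, 1),
    pos = as.integer(purrr::map_chr(fields, 2)),
    ref = toupper(purrr::map_chr(fields, 4)),
    alt = toupper(purrr::map_chr(fields, 5)),
    info = purrr::map_chr(fields, ~ if (length(.x) >= 8L) .x[8] else "")
  )
  tbl$transcript_id <- stringr::str_match(tbl$info, "TRANSCRIPT=([^;]+)")[, 2]
  if (!is.null(transcript_map)) {
    map <- readr::read_tsv(transcript_map, show_col_types = FALSE)
    tbl <- tbl %>%
      dplyr::select(-"transcript_id") %>%
      dplyr::left_join(map, by = c("chrom", "pos"))
  }
  dplyr::select(tbl, -"info")
}

# 0-based offset of genomic position `pos0` within the spliced CDS of a
# transcript (strand-aware); NA when the position is not in the CDS
cds_offset_of <- function(ref, transcript_id, pos0) {
  cds <- dplyr::arrange(ref$cds[ref$cds$transcript_id == transcript_id, ],
                        .data$start)
  if (nrow(cds) == 0L) return(NA_integer_)
  minus <- cds$strand[1] == "-"
  ord <- if (minus) rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
  cum <- 0L
  for (i in ord) {
    len <- cds$end[i] - cds$start[i]
    if (pos0 >= cds$start[i] && pos0 < cds$end[i]) {
      within <- if (minus) cds$end[i] - 1L - pos0 else pos0 - cds$start[i]
      return(cum + within)
    }
    cum <- cum + len
  }
  NA_integer_
}

#' Validate frameshift variants against a reference
#'
#' Checks that each variant is frameshifting (`|len(ref) - len(alt)|` not a
#' multiple of 3), that the REF allele matches the genome at POS, and
#' computes the 0-based offset of the variant within the spliced CDS of its
#' transcript. Variants whose REF does not match are a hard error (corrupt
#' VCF/reference pairing); in-frame indels are rejected.
#'
#' @param ref A `reference_model`.
#' @param variants Tibble from [read_frameshift_vcf()].
#' @return The input tibble with added columns `cds_offset` (offset of the
#'   first REF base in sense CDS coordinates) and `strand`.
#' @export
frameshift_variants <- function(ref, variants) {
  out <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    delta <- abs(nchar(v$ref) - nchar(v$alt))
    if (delta %% 3L == 0L) {
      abort(sprintf("variant %s:%d %s>%s is not frameshifting",
                    v$chrom, v$pos, v$ref, v$alt))
    }
    genome_ref <- substr(ref$chromosomes[[v$chrom]], v$pos,
                         v$pos + nchar(v$ref) - 1L)
    strand <- ref$cds$strand[ref$cds$transcript_id == v$transcript_id][1]
    if (is.na(strand)) {
      abort(paste0("transcript without CDS in reference: ", v$transcript_id))
    }
    if (genome_ref != v$ref) {
      abort(sprintf("REF mismatch at %s:%d (VCF %s, genome %s)",
                    v$chrom, v$pos, v$ref, genome_ref))
    }
    pos0 <- v$pos - 1L
    # sense-space first edited base: on minus strand the genomically last
    # REF base is the transcription-direction first
    sense_pos0 <- if (strand == "-") pos0 + nchar(v$ref) - 1L else pos0
    off <- cds_offset_of(ref, v$transcript_id, sense_pos0)
    if (is.na(off)) {
      abort(sprintf("variant %s:%d is outside the CDS of %s",
                    v$chrom, v$pos, v$transcript_id))
    }
    dplyr::mutate(v, cds_offset = off, strand = strand)
  })
  dplyr::bind_rows(out)
}

#' Apply a frameshift edit to a coding sequence
#'
#' Replaces the REF allele by the ALT allele at the variant's CDS offset.
#' The sequence should be the spliced CDS with enough downstream
#' continuation appended for the shifted frame to reach a stop codon.
#'
#' @param cds_plus_downstream Sense-strand nucleotide string.
#' @param variant One row of [frameshift_variants()] output (fields
#'   `cds_offset`, `ref`, `alt`; for minus-strand variants REF/ALT are
#'   reverse-complemented to sense space internally).
#' @return The edited nucleotide string.
#' @export
apply_frameshift <- function(cds_plus_downstream, variant) {
  ref_allele <- variant$ref
  alt_allele <- variant$alt
  if (!is.null(variant$strand) && isTRUE(variant$strand == "-")) {
    ref_allele <- reverse_complement(ref_allele)
    alt_allele <- reverse_complement(alt_allele)
  }
  off <- variant$cds_offset
  found <- substr(cds_plus_downstream, off + 1L, off + nchar(ref_allele))
  if (found != ref_allele) {
    abort(sprintf("REF allele %s not found at CDS offset %d (saw %s)",
                  ref_allele, off, found))
  }
  paste0(substr(cds_plus_downstream, 1L, off), alt_allele,
         substr(cds_plus_downstream, off + nchar(ref_allele) + 1L,
                nchar(cds_plus_downstream)))
}

spliced_sequence <- function(ref, tbl) {
  tbl <- dplyr::arrange(tbl, .data$start)
  pieces <- purrr::map_chr(seq_len(nrow(tbl)), function(i) {
    substr(ref$chromosomes[[tbl$chrom[i]]], tbl$start[i] + 1L, tbl$end[i])
  })
  s <- paste(pieces, collapse = "")
  if (nrow(tbl) > 0L && tbl$strand[1] == "-") reverse_complement(s) else s
}

# CDS + downstream continuation in sense space for tail translation.
# "spliced": rest of the spliced transcript (3'UTR exons), then the genomic
# continuation past the transcript end; "genomic": genomic continuation
# immediately after the last CDS base.
cds_with_downstream <- function(ref, transcript_id,
                                readthrough = c("spliced", "genomic"),
                                max_tail_nt = 10000L) {
  readthrough <- match.arg(readthrough)
  cds <- ref$cds[ref$cds$transcript_id == transcript_id, ]
  if (nrow(cds) == 0L) abort(paste0("no CDS for transcript ", transcript_id))
  ex <- ref$exons[ref$exons$transcript_id == transcript_id, ]
  minus <- cds$strand[1] == "-"
  chrom <- cds$chrom[1]
  chrom_len <- nchar(ref$chromosomes[[chrom]])
  cds_seq <- spliced_sequence(ref, cds)

  if (readthrough == "genomic") {
    last3 <- if (minus) min(cds$start) else max(cds$end)
    down <- if (minus) {
      genomic_slice(ref, chrom, max(0L, last3 - max_tail_nt), last3, "-")
    } else {
      genomic_slice(ref, chrom, last3, min(chrom_len, last3 + max_tail_nt), "+")
    }
    return(list(seq = paste0(cds_seq, down), cds_len = nchar(cds_seq)))
  }

  # spliced-first: exonic sequence 3' of the CDS end, then genomic past the
  # transcript end
  cds_hi <- max(cds$end); cds_lo <- min(cds$start)
  if (minus) {
    utr <- ex[ex$start < cds_lo, ]
    utr$end <- pmin(utr$end, cds_lo)
  } else {
    utr <- ex[ex$end > cds_hi, ]
    utr$start <- pmax(utr$start, cds_hi)
  }
  utr_seq <- if (nrow(utr) > 0L) spliced_sequence(ref, utr) else ""
  tx_end3 <- if (minus) min(ex$start) else max(ex$end)
  genomic_down <- if (minus) {
    genomic_slice(ref, chrom, max(0L, tx_end3 - max_tail_nt), tx_end3, "-")
  } else {
    genomic_slice(ref, chrom, tx_end3, min(chrom_len, tx_end3 + max_tail_nt), "+")
  }
  list(seq = paste0(cds_seq, utr_seq, genomic_down), cds_len = nchar(cds_seq))
}

#' Build mutant proteins from frameshift variants
#'
#' For each validated variant, edits the spliced CDS (plus downstream
#' continuation), translates from the CDS start, and splits the result into
#' the canonical `prefix` (residues fully 5' of the first codon touching
#' the edit) and the novel `tail` (residues from that codon to the first
#' stop in the shifted frame, stop excluded). When no stop is reached
#' within the appended sequence, the record is truncated and flagged
#' `no_stop_found`.
#'
#' @param ref A `reference_model`.
#' @param variants Output of [frameshift_variants()].
#' @param readthrough `"spliced"` (default: read through the spliced
#'   transcript first, then the genomic 3' continuation) or `"genomic"`
#'   (genomic continuation immediately after the CDS).
#' @param max_tail_nt Bound on the downstream continuation, in nt.
#' @return Tibble (id, transcript_id, chrom, pos, ref, alt, prefix, tail,
#'   full_seq, no_stop_found).
#' @export
build_mutant_proteins <- function(ref, variants,
                                  readthrough = c("spliced", "genomic"),
                                  max_tail_nt = 10000L) {
  readthrough <- match.arg(readthrough)
  out <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ctx <- cds_with_downstream(ref, v$transcript_id, readthrough, max_tail_nt)
    mutant <- apply_frameshift(ctx$seq, v)
    prot <- mutant_protein(mutant, v)
    tibble::tibble(
      id = sprintf("FS|%s|%s:%d|%s>%s", v$transcript_id, v$chrom, v$pos,
                   v$ref, v$alt),
      transcript_id = v$transcript_id, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt, prefix = prot$prefix, tail = prot$tail,
      full_seq = prot$full_seq, no_stop_found = prot$no_stop_found)
  })
  dplyr::bind_rows(out)
}

#' Translate an edited coding sequence into a mutant protein
#'
#' @param mutant_nt Edited sense-strand nucleotide string starting at the
#'   CDS start.
#' @param variant One row with field `cds_offset` locating the edit.
#' @return A list with `prefix`, `tail`, `full_seq` and `no_stop_found`.
#' @export
mutant_protein <- function(mutant_nt, variant) {
  edit_codon <- variant$cds_offset %/% 3L
  aa <- translate_frame(mutant_nt, 0L)
  prefix <- substr(aa, 1L, edit_codon)
  rest <- substr(aa, edit_codon + 1L, nchar(aa))
  stop_at <- stringr::str_locate(rest, stringr::fixed("*"))[1, "start"]
  no_stop <- is.na(stop_at)
  tail <- if (no_stop) rest else substr(rest, 1L, stop_at - 1L)
  # drop any X from reference-edge padding
  tail <- sub("X.*$", "", tail)
  list(prefix = prefix, tail = tail,
       full_seq = paste0(prefix, tail), no_stop_found = no_stop)
}

#' Match peptides against frameshift mutant proteins
#'
#' A peptide is frameshift evidence when it occurs as an exact substring
#' (I and L distinguished) of a mutant protein **and** the match overlaps
#' at least one residue of the novel tail; matches confined to the
#' canonical prefix are not reported.
#'
#' @param peptides Character vector or tibble with a `sequence` column.
#' @param mutants Output of [build_mutant_proteins()].
#' @return Tibble (sequence, id, transcript_id, offset, spans_junction):
#'   `offset` is the 0-based match offset in the mutant protein and
#'   `spans_junction` indicates the match crosses the prefix/tail boundary.
#' @export
match_frameshift <- function(peptides, mutants) {
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  seqs <- unique(seqs)
  rows <- purrr::map(seqs, function(p) {
    k <- nchar(p)
    hit_rows <- purrr::map(seq_len(nrow(mutants)), function(i) {
      m <- mutants[i, ]
      locs <- stringr::str_locate_all(m$full_seq, stringr::fixed(p))[[1]]
      if (nrow(locs) == 0L) return(NULL)
      off <- as.integer(locs[, "start"]) - 1L
      in_tail <- off + k > nchar(m$prefix)
      off <- off[in_tail]
      if (length(off) == 0L) return(NULL)
      tibble::tibble(sequence = p, id = m$id, transcript_id = m$transcript_id,
                     offset = off, spans_junction = off < nchar(m$prefix))
    })
    dplyr::bind_rows(hit_rows)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(sequence = character(), id = character(),
                          transcript_id = character(), offset = integer(),
                          spans_junction = logical())
  }
  out
}
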