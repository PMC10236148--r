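#' Build the pre-mRNA three-frame translation search space
#'
#' For every protein-coding gene, translates the unspliced sense pre-mRNA in
#' frames 0/1/2, splits each frame translation at stop codons (`*`) and
#' ambiguous residues (`X`) into maximal clean segments, and keeps segments
#' of at least `min_len` residues. Each segment carries an `anchor`, the
#' genomic coordinate of the first base of its first codon (for minus-strand
#' genes the genomically highest base of that codon), from which the genomic
#' coordinates of any matched peptide can be recovered exactly.
#'
#' @param ref A `reference_model` from [load_reference()].
#' @param min_len Minimum segment length in residues. The default 7 is the
#'   shortest peptide the downstream matching considers; shorter segments
#'   cannot host a match.
#' @return A tibble of class `threeft_index` with columns gene_id, chrom,
#'   strand, frame, segment_index, anchor, aa_seq, length.
#' @export
build_3ft <- function(ref, min_len = 7L) {
  coding <- ref$genes[ref$genes$biotype == "protein_coding", ]
  rows <- purrr::pmap(coding, function(gene_id, gene_name, biotype, chrom,
                                       strand, start, end) {
    pre <- premrna_sequence(ref, gene_id)
    purrr::map(0:2, function(frame) {
      aa <- translate_frame(pre, frame)
      segs <- split_translation(aa)
      if (nrow(segs) == 0L) return(NULL)
      segs <- segs[nchar(segs$aa_seq) >= min_len, , drop = FALSE]
      if (nrow(segs) == 0L) return(NULL)
      # sense-space nt offset of the segment's first codon
      sense_off <- frame + 3L * segs$aa_start
      anchor <- if (strand == "+") start + sense_off else end - 1L - sense_off
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand, frame = frame,
        segment_index = seq_len(nrow(segs)) - 1L,
        anchor = anchor, aa_seq = segs$aa_seq, length = nchar(segs$aa_seq)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::list_flatten(rows))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      frame = integer(), segment_index = integer(), anchor = integer(),
      aa_seq = character(), length = integer()
    )
  }
  class(out) <- c("threeft_index", class(out))
  out
}

# split an amino-acid string at '*' and 'X'; returns aa_start (0-based
# residue offset within the frame translation) and the clean substring
split_translation <- function(aa) {
  if (nchar(aa) == 0L) {
    return(tibble::tibble(aa_start = integer(), aa_seq = character()))
  }
  pieces <- stringr::str_locate_all(aa, "[^*X]+")[[1]]
  tibble::tibble(
    aa_start = as.integer(pieces[, "start"]) - 1L,
    aa_seq = stringr::str_sub(aa, pieces[, "start"], pieces[, "end"])
  )
}

#' Genomic interval of an amino-acid window within a 3FT segment
#'
#' Maps a residue window of a translated segment back to genomic
#' coordinates. On the plus strand the interval is
#' `[anchor + 3*aa_start, anchor + 3*(aa_start+aa_len))`; on the minus
#' strand `[anchor - 3*(aa_start+aa_len) + 1, anchor - 3*aa_start + 1)`.
#' The interval length is always `3 * aa_len`.
#'
#' @param segment A one-row slice of a `threeft_index` (or a list with
#'   fields chrom, strand, anchor, aa_seq).
#' @param aa_start 0-based residue offset of the window within the segment.
#' @param aa_len Window length in residues.
#' @return Tibble (chrom, start, end, strand) with one row.
#' @export
segment_to_genomic <- function(segment, aa_start, aa_len) {
  if (aa_start < 0L || aa_len < 1L || aa_start + aa_len > nchar(segment$aa_seq)) {
    abort("amino-acid window out of range for segment")
  }
  if (segment$strand == "+") {
    start <- segment$anchor + 3L * aa_start
    end <- segment$anchor + 3L * (aa_start + aa_len)
  } else {
    start <- segment$anchor - 3L * (aa_start + aa_len) + 1L
    end <- segment$anchor - 3L * aa_start + 1L
  }
  tibble::tibble(chrom = segment$chrom, start = as.integer(start),
                 end = as.integer(end), strand = segment$strand)
}

#' Write a 3FT index to FASTA with coordinate-recoverable headers
#'
#' Headers follow the fixed grammar
#' `>3FT|{gene_id}|{chrom}|{strand}|{frame}|{anchor}|{segment_index}` so the
#' genomic coordinates of any matched peptide can be recovered from the
#' header alone.
#'
#' @param segments A `threeft_index` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_3ft_fasta <- function(segments, path) {
  headers <- sprintf("3FT|%s|%s|%s|%d|%d|%d",
                     segments$gene_id, segments$chrom, segments$strand,
                     segments$frame, segments$anchor, segments$segment_index)
  set <- Biostrings::AAStringSet(segments$aa_seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Parse a 3FT FASTA header back to segment metadata
#'
#' @param header Header string (with or without the leading `>`).
#' @return Tibble (gene_id, chrom, strand, frame, anchor, segment_index).
#' @export
parse_3ft_header <- function(header) {
  header <- sub("^>", "", header)
  fields <- stringr::str_split(header, stringr::fixed("|"))[[1]]
  if (length(fields) != 7L || fields[1] != "3FT") {
    abort(sprintf("malformed 3FT header (expected 7 '|' fields starting '3FT'): %s",
                  header))
  }
  if (!fields[4] %in% c("+", "-")) abort("malformed 3FT header: strand field")
  frame <- suppressWarnings(as.integer(fields[5]))
  anchor <- suppressWarnings(as.integer(fields[6]))
  idx <- suppressWarnings(as.integer(fields[7]))
  if (is.na(frame) || !frame %in% 0:2) abort("malformed 3FT header: frame field")
  if (is.na(anchor)) abort("malformed 3FT header: anchor field")
  if (is.na(idx)) abort("malformed 3FT header: segment_index field")
  tibble::tibble(gene_id = fields[2], chrom = fields[3], strand = fields[4],
                 frame = frame, anchor = anchor, segment_index = idx)
}

#' Read a 3FT FASTA written by [write_3ft_fasta()]
#'
#' @param path FASTA path.
#' @return A `threeft_index` tibble equivalent to the one written.
#' @export
read_3ft_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  meta <- dplyr::bind_rows(purrr::map(names(set), parse_3ft_header))
  out <- dplyr::mutate(meta, aa_seq = unname(as.character(set)),
                       length = nchar(.data$aa_seq))
  out <- dplyr::select(out, "gene_id", "chrom", "strand", "frame",
                       "segment_index", "anchor", "aa_seq", "length")
  class(out) <- c("threeft_index", class(out))
  out
}
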