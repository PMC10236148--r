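#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
NEAR_COGNATE_STARTS <- c("ATG", "CTG", "TTG", "GTG", "ACG")

#' Load a genome and its gene annotation into a reference model
#'
#' Reads a genome FASTA and an ENSEMBL-style GTF and returns a validated
#' `reference_model`: chromosome sequences plus tidy gene / transcript /
#' exon / CDS tables. All internal coordinates are 0-based half-open
#' (`[start, end)`); the 1-based closed GTF convention is converted at this
#' boundary and BED output converts back symmetrically.
#'
#' Chromosome names in the annotation are resolved against the FASTA after
#' an optional "chr" prefix normalisation, so "chr1" and "1" interoperate.
#'
#' @param genome Path to a genome FASTA file (wrapped or unwrapped).
#' @param annotation Path to a GTF file with `gene_id`, `transcript_id` and
#'   `gene_biotype` attributes and gene/transcript/exon/CDS features.
#' @return An object of class `reference_model`: a list with
#'   * `chromosomes`: named uppercase character vector of sequences (ACGTN),
#'   * `genes`: tibble (gene_id, gene_name, biotype, chrom, strand, start, end),
#'   * `transcripts`: tibble (transcript_id, gene_id),
#'   * `exons`: tibble (transcript_id, gene_id, chrom, strand, start, end),
#'     sorted in ascending genomic order within each transcript,
#'   * `cds`: tibble with the same columns (possibly empty).
#'
#' Genes whose biotype is not `protein_coding` are retained but only
#' protein-coding genes enter [build_3ft()].
#' @export
load_reference <- function(genome, annotation) {
  seqs <- Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chromosomes <- toupper(as.character(seqs))
  bad <- stringr::str_detect(chromosomes, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("chromosome ", names(chromosomes)[bad][1],
                 " contains characters outside ACGTN"))
  }

  gtf <- rtracklayer::import(annotation, format = "gtf")
  gtf_tbl <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gtf)),
    start = GenomicRanges::start(gtf) - 1L,  # GTF 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gtf),
    strand = as.character(GenomicRanges::strand(gtf)),
    feature = as.character(gtf$type),
    gene_id = gtf$gene_id,
    transcript_id = if ("transcript_id" %in% names(S4Vectors::mcols(gtf))) {
      gtf$transcript_id
    } else {
      NA_character_
    },
    gene_name = if ("gene_name" %in% names(S4Vectors::mcols(gtf))) {
      gtf$gene_name
    } else {
      NA_character_
    },
    biotype = if ("gene_biotype" %in% names(S4Vectors::mcols(gtf))) {
      gtf$gene_biotype
    } else {
      NA_character_
    }
  )
  gtf_tbl$chrom <- resolve_chrom_names(gtf_tbl$chrom, names(chromosomes))

  genes <- gtf_tbl %>%
    dplyr::filter(.data$feature == "gene") %>%
    dplyr::transmute(
      gene_id = .data$gene_id,
      gene_name = dplyr::coalesce(.data$gene_name, .data$gene_id),
      biotype = dplyr::coalesce(.data$biotype, "protein_coding"),
      chrom = .data$chrom, strand = .data$strand,
      start = .data$start, end = .data$end
    )
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("gene_id with multiple spans not supported: ",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  }

  exons <- gtf_tbl %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "start", "end") %>%
    dplyr::arrange(.data$transcript_id, .data$start)
  cds <- gtf_tbl %>%
    dplyr::filter(.data$feature == "CDS") %>%
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "start", "end") %>%
    dplyr::arrange(.data$transcript_id, .data$start)
  transcripts <- gtf_tbl %>%
    dplyr::filter(.data$feature == "transcript") %>%
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  if (nrow(transcripts) == 0L && nrow(exons) > 0L) {
    transcripts <- dplyr::distinct(exons, .data$transcript_id, .data$gene_id)
  }

  ref <- structure(
    list(chromosomes = chromosomes, genes = genes,
         transcripts = transcripts, exons = exons, cds = cds),
    class = "reference_model"
  )
  validate_reference(ref)
  ref
}

resolve_chrom_names <- function(x, known) {
  out <- x
  missing <- !(out %in% known)
  # try toggling a "chr" prefix for unresolved names
  toggled <- ifelse(stringr::str_starts(out[missing], "chr"),
                    stringr::str_remove(out[missing], "^chr"),
                    paste0("chr", out[missing]))
  ok <- toggled %in% known
  out[missing][ok] <- toggled[ok]
  still <- !(out %in% known)
  if (any(still)) {
    abort(paste0("annotation references unknown chromosome: ",
                 unique(x[still])[1]))
  }
  out
}

validate_reference <- function(ref) {
  lens <- nchar(ref$chromosomes)
  for (tbl_name in c("genes", "exons", "cds")) {
    tbl <- ref[[tbl_name]]
    if (nrow(tbl) == 0L) next
    if (any(tbl$end <= tbl$start)) {
      abort(paste0("empty or inverted interval in ", tbl_name))
    }
    out_of_range <- tbl$start < 0L | tbl$end > lens[tbl$chrom]
    if (any(out_of_range)) {
      bad <- tbl[which(out_of_range)[1], ]
      abort(sprintf("%s interval [%d,%d) outside chromosome %s",
                    tbl_name, bad$start, bad$end, bad$chrom))
    }
  }
  # exons non-overlapping and ascending within a transcript
  by_tx <- split(ref$exons, ref$exons$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1L && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      abort(paste0("overlapping exons in transcript ", tx$transcript_id[1]))
    }
  }
  invisible(ref)
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model>\n")
  cat(sprintf("  %d chromosome(s), %s nt total\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  cat(sprintf("  %d gene(s) (%d protein_coding), %d transcript(s), %d exon(s)\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

gene_row <- function(ref, gene_id) {
  row <- ref$genes[ref$genes$gene_id == gene_id, ]
  if (nrow(row) == 0L) abort(paste0("unknown gene_id: ", gene_id))
  row
}

#' Unspliced pre-mRNA sequence of a gene
#'
#' Returns the sense-strand sequence of the full gene span. Minus-strand
#' genes return the reverse complement of the genomic slice, so the result
#' always reads 5' to 3' in the direction of transcription.
#'
#' @param ref A `reference_model` from [load_reference()].
#' @param gene_id Gene identifier present in `ref$genes`.
#' @return A single nucleotide string of length `end - start`.
#' @export
premrna_sequence <- function(ref, gene_id) {
  g <- gene_row(ref, gene_id)
  s <- substr(ref$chromosomes[[g$chrom]], g$start + 1L, g$end)
  if (g$strand == "-") s <- reverse_complement(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' @param nt Nucleotide string over ACGTN.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(nt) {
  if (nchar(nt) == 0L) return(nt)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Translate a nucleotide string in a given frame
#'
#' Standard-code translation starting at offset `frame`. Stop codons are
#' emitted as `*`, codons containing `N` as `X`, and a trailing partial
#' codon is dropped.
#'
#' @param nt Nucleotide string (ACGTN).
#' @param frame Integer offset 0, 1 or 2.
#' @return Amino-acid string with one letter per complete codon (possibly
#'   empty).
#' @export
translate_frame <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  n <- nchar(nt) - frame
  if (n < 3L) return("")
  n_codons <- n %/% 3L
  sub <- substr(nt, frame + 1L, frame + 3L * n_codons)
  as.character(Biostrings::translate(
    Biostrings::DNAString(sub),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

#' Derive intron intervals for each transcript
#'
#' Introns are the gaps between consecutive exons of a transcript, in
#' 0-based half-open coordinates.
#'
#' @param ref A `reference_model`.
#' @return Tibble (transcript_id, gene_id, chrom, strand, start, end);
#'   zero rows for single-exon transcripts.
#' @export
transcript_introns <- function(ref) {
  ref$exons %>%
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::reframe(intron_start = .data$end[-dplyr::n()],
                   intron_end = .data$start[-1]) %>%
    dplyr::transmute(.data$transcript_id, .data$gene_id, .data$chrom,
                     .data$strand, start = .data$intron_start,
                     end = .data$intron_end)
}

genomic_slice <- function(ref, chrom, start, end, strand = "+") {
  s <- substr(ref$chromosomes[[chrom]], start + 1L, end)
  if (strand == "-") reverse_complement(s) else s
}
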