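#' Scan upstream of a peptide for in-frame near-cognate start codons
#'
#' Walks 5'-ward from the peptide's first codon in steps of 3 (the
#' peptide's own reading frame; an out-of-frame start cannot produce the
#' peptide) and reports every near-cognate start codon
#' (ATG, CTG, TTG, GTG, ACG). The scan stops at, and excludes, the first
#' stop codon, the reference edge, or the host gene boundary
#' (`bound = "gene"`, the default, since 3FT segments are gene-scoped).
#'
#' @param ref A `reference_model`.
#' @param interval One-row tibble or list (chrom, start, end, strand): the
#'   peptide's genomic interval from [peptides_to_bed()].
#' @param gene_id Host gene bounding the scan; required when
#'   `bound = "gene"`.
#' @param bound `"gene"` or `"chromosome"`.
#' @return Tibble (codon, genomic_position, upstream_offset_nt, rank) in
#'   nearest-first order; `genomic_position` is the transcription-direction
#'   5' base of the codon and `upstream_offset_nt` is a positive multiple
#'   of 3. Zero rows when a stop codon sits immediately upstream.
#' @export
scan_upstream <- function(ref, interval, gene_id = NULL,
                          bound = c("gene", "chromosome")) {
  bound <- match.arg(bound)
  chrom_len <- nchar(ref$chromosomes[[interval$chrom]])
  if (bound == "gene") {
    if (is.null(gene_id)) abort("gene_id required when bound = \"gene\"")
    g <- gene_row(ref, gene_id)
    lo <- g$start; hi <- g$end
  } else {
    lo <- 0L; hi <- chrom_len
  }
  minus <- interval$strand == "-"
  hits <- list()
  offset <- 3L
  repeat {
    if (minus) {
      p5 <- interval$end - 1L + offset       # transcription 5' base
      if (p5 >= hi) break
      codon <- reverse_complement(
        substr(ref$chromosomes[[interval$chrom]], p5 - 1L, p5 + 1L))
    } else {
      p5 <- interval$start - offset
      if (p5 < lo) break
      codon <- substr(ref$chromosomes[[interval$chrom]], p5 + 1L, p5 + 3L)
    }
    if (codon %in% STOP_CODONS) break
    if (codon %in% NEAR_COGNATE_STARTS) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        codon = codon, genomic_position = as.integer(p5),
        upstream_offset_nt = as.integer(offset))
    }
    offset <- offset + 3L
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(codon = character(), genomic_position = integer(),
                          upstream_offset_nt = integer(), rank = integer()))
  }
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Extract the 203-nt context window around a candidate start codon
#'
#' 100 nt upstream + the codon + 100 nt downstream on the coding strand,
#' N-padded at reference edges, so the codon always occupies positions
#' 101-103 (1-based) of the returned string. This is the fixed-width input
#' expected by translation-initiation-site scorers.
#'
#' @param ref A `reference_model`.
#' @param chrom,position,strand Location of the start codon;
#'   `position` is the transcription-direction 5' base of the codon (for
#'   minus-strand hits, its genomically highest base), as returned by
#'   [scan_upstream()].
#' @return A list with `sequence` (203-character string) and `center_codon`.
#' @export
tis_window <- function(ref, chrom, position, strand = "+") {
  chrom_seq <- ref$chromosomes[[chrom]]
  if (is.null(chrom_seq)) abort(paste0("unknown chromosome: ", chrom))
  n <- nchar(chrom_seq)
  if (strand == "+") {
    lo <- position - 100L; hi <- position + 103L  # [lo, hi)
  } else {
    lo <- position - 102L; hi <- position + 101L
  }
  pad_left <- max(0L, -lo)
  pad_right <- max(0L, hi - n)
  core <- substr(chrom_seq, max(lo, 0L) + 1L, min(hi, n))
  seq <- paste0(strrep("N", pad_left), core, strrep("N", pad_right))
  if (strand == "-") seq <- reverse_complement(seq)
  stopifnot(nchar(seq) == 203L)
  list(sequence = seq, center_codon = substr(seq, 101L, 103L))
}

#' Score a candidate translation initiation site
#'
#' Delegates to a pluggable scorer taking the 203-nt window string and
#' returning a value in `[0, 1]`; a score strictly greater than 0.5 is a
#' positive prediction. The bundled default, [kozak_scorer()], is a simple
#' position-weight heuristic over the Kozak consensus context and is *not*
#' a trained TIS model; swap in any scorer with the same signature for
#' production use.
#'
#' @param window Output of [tis_window()] (or a 203-nt string).
#' @param scorer Function from window string to `[0, 1]`.
#' @return A list with `score` and `positive` (`score > 0.5`).
#' @export
score_tis <- function(window, scorer = kozak_scorer) {
  seq <- if (is.list(window)) window$sequence else window
  s <- scorer(seq)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    abort("TIS scorer must return a single value in [0, 1]")
  }
  list(score = as.numeric(s), positive = s > 0.5)
}

#' Kozak-context position-weight heuristic TIS scorer
#'
#' Scores the local context of the candidate start codon against the Kozak
#' consensus (gccRccATGG): the strongly informative positions are -3
#' (purine, ideally A) and +4 (G), with small contributions from the minor
#' consensus positions and an ATG bonus over near-cognate codons. The raw
#' weight sum is scaled to `[0, 1]`. A deliberately simple, fully
#' deterministic baseline - not a trained model.
#'
#' @param seq 203-nt window string with the codon at positions 101-103.
#' @return Score in `[0, 1]`.
#' @export
kozak_scorer <- function(seq) {
  stopifnot(nchar(seq) == 203L)
  at <- function(i) substr(seq, i, i)  # 1-based
  score <- 0
  # position -3 (98): A=2, G=1.5; position +4 (104): G=2
  score <- score + switch(at(98), A = 2, G = 1.5, 0)
  score <- score + if (at(104) == "G") 2 else 0
  # minor consensus positions -6..-4 (95:97) ~ gcc, -2..-1 (99:100) ~ cc
  minor <- c(`95` = "G", `96` = "C", `97` = "C", `99` = "C", `100` = "C")
  score <- score + sum(purrr::imap_dbl(minor, ~ as.numeric(at(as.integer(.y)) == .x))) * 0.4
  # AUG start bonus over near-cognate codons
  if (substr(seq, 101, 103) == "ATG") score <- score + 2
  score / 8  # max attainable: 2 + 2 + 2 + 5*0.4 = 8
}

#' Per-exon in-frame codon coordinates (frame propagation across exons)
#'
#' For every exon that has a downstream intron, computes the genomic
#' coordinate of the first codon in-frame with the upstream coding
#' sequence, propagating the reading frame across exons in transcription
#' order starting from the first exon's 5' end. This is the reference grid
#' against which intronic peptides are tested for intron-retention
#' compatibility.
#'
#' The default `method = "frame_aware"` places the in-frame coordinate at
#' `exon 5' start - (cumulative exonic length so far mod 3)` (mirrored on
#' the minus strand), which provably aligns with the codon grid obtained by
#' splicing and translating: peptides starting on that grid inside the
#' retained intron are in-frame. `method = "literal"` reproduces a
#' published pseudocode variant of this bookkeeping verbatim (including its
#' remainder arithmetic, which differs by one base in some configurations);
#' it is provided for comparison only.
#'
#' @param ref A `reference_model`.
#' @param method `"frame_aware"` (default) or `"literal"`.
#' @return Tibble of `exon_frame_record`s: (transcript_id, chrom, strand,
#'   exon_start, exon_end, inframe_coordinate, intron_start, intron_end).
#'   Single-exon transcripts contribute no rows.
#' @export
exon_frame_table <- function(ref, method = c("frame_aware", "literal")) {
  method <- match.arg(method)
  rows <- list()
  for (tx in unique(ref$exons$transcript_id)) {
    ex <- dplyr::arrange(ref$exons[ref$exons$transcript_id == tx, ], .data$start)
    if (nrow(ex) < 2L) next
    minus <- ex$strand[1] == "-"
    ord <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    cum <- 0L
    rem_lit <- 0L  # literal-mode remainder state
    for (k in seq_along(ord)) {
      i <- ord[k]
      has_downstream <- k < length(ord)
      len <- ex$end[i] - ex$start[i]
      if (has_downstream) {
        if (method == "frame_aware") {
          dangling <- cum %% 3L
          inframe <- if (minus) (ex$end[i] - 1L) + dangling
                     else ex$start[i] - dangling
        } else {
          inframe <- if (minus) (ex$end[i] - 1L) + rem_lit
                     else ex$start[i] - rem_lit
        }
        j <- ord[k + 1L]
        intron_start <- if (minus) ex$end[j] else ex$end[i]
        intron_end <- if (minus) ex$start[i] else ex$start[j]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          transcript_id = tx, chrom = ex$chrom[1], strand = ex$strand[1],
          exon_start = ex$start[i], exon_end = ex$end[i],
          inframe_coordinate = as.integer(inframe),
          intron_start = as.integer(intron_start),
          intron_end = as.integer(intron_end))
      }
      cum <- cum + len
      leftover <- (len - rem_lit) %% 3L
      if (leftover > 0L) rem_lit <- 3L - leftover  # literal: unchanged when 0
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(transcript_id = character(), chrom = character(),
                          strand = character(), exon_start = integer(),
                          exon_end = integer(), inframe_coordinate = integer(),
                          intron_start = integer(), intron_end = integer())
  }
  out
}

#' Is an intronic peptide in-frame with its upstream exon?
#'
#' A retained intron can only yield the peptide when the peptide's codon
#' grid continues the upstream exon's reading frame: on the plus strand
#' `(peptide 5' start - inframe_coordinate) mod 3 == 0`, mirrored on the
#' minus strand, where the peptide 5' start is its transcription-direction
#' first base.
#'
#' @param interval One-row tibble or list (chrom, start, end, strand).
#' @param record One row of [exon_frame_table()] output whose intron the
#'   peptide intersects.
#' @return Logical.
#' @export
intron_inframe <- function(interval, record) {
  if (!(interval$start < record$intron_end && interval$end > record$intron_start)) {
    abort("peptide interval does not intersect the record's downstream intron")
  }
  if (record$strand == "+") {
    (interval$start - record$inframe_coordinate) %% 3L == 0L
  } else {
    (record$inframe_coordinate - (interval$end - 1L)) %% 3L == 0L
  }
}

#' Intron-retention verdicts for a peptide BED set
#'
#' Intersects peptide intervals with the introns of [exon_frame_table()]
#' and evaluates the in-frame condition per (peptide, transcript),
#' reporting per-transcript detail plus an any-transcript verdict.
#'
#' @param bed Tibble with chrom, start, end, name, strand.
#' @param ref A `reference_model`.
#' @param method Passed to [exon_frame_table()].
#' @return Tibble (name, chrom, start, end, strand, transcript_id,
#'   intron_start, intron_end, in_frame, any_in_frame).
#' @export
ir_check <- function(bed, ref, method = "frame_aware") {
  records <- exon_frame_table(ref, method = method)
  rows <- purrr::map(seq_len(nrow(bed)), function(i) {
    iv <- bed[i, ]
    rec <- records[records$chrom == iv$chrom & records$strand == iv$strand &
                     records$intron_start < iv$end &
                     records$intron_end > iv$start, ]
    if (nrow(rec) == 0L) return(NULL)
    tibble::tibble(
      name = iv$name, chrom = iv$chrom, start = iv$start, end = iv$end,
      strand = iv$strand, transcript_id = rec$transcript_id,
      intron_start = rec$intron_start, intron_end = rec$intron_end,
      in_frame = purrr::map_lgl(seq_len(nrow(rec)),
                                ~ intron_inframe(iv, rec[.x, ])))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(name = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), transcript_id = character(),
                          intron_start = integer(), intron_end = integer(),
                          in_frame = logical(), any_in_frame = logical()))
  }
  out %>%
    dplyr::group_by(.data$name, .data$chrom, .data$start, .data$end,
                    .data$strand) %>%
    dplyr::mutate(any_in_frame = any(.data$in_frame)) %>%
    dplyr::ungroup()
}

#' Upstream ORF report for a peptide BED set
#'
#' Runs [scan_upstream()], [tis_window()] and [score_tis()] for each
#' peptide interval.
#'
#' @param bed Output of [peptides_to_bed()] (needs the gene_id column when
#'   `bound = "gene"`).
#' @param ref A `reference_model`.
#' @param scorer TIS scorer, see [score_tis()].
#' @param bound Scan bound, see [scan_upstream()].
#' @return Tibble (name, gene_id, codon, genomic_position,
#'   upstream_offset_nt, rank, tis_score, tis_positive).
#' @export
orf_scan <- function(bed, ref, scorer = kozak_scorer, bound = "gene") {
  rows <- purrr::map(seq_len(nrow(bed)), function(i) {
    iv <- bed[i, ]
    hits <- scan_upstream(ref, iv, gene_id = iv$gene_id, bound = bound)
    if (nrow(hits) == 0L) return(NULL)
    scored <- purrr::map(hits$genomic_position, function(p) {
      score_tis(tis_window(ref, iv$chrom, p, iv$strand), scorer = scorer)
    })
    dplyr::mutate(hits, name = iv$name, gene_id = iv$gene_id, .before = 1L,
                  tis_score = purrr::map_dbl(scored, "score"),
                  tis_positive = purrr::map_lgl(scored, "positive"))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(name = character(), gene_id = character(),
                          codon = character(), genomic_position = integer(),
                          upstream_offset_nt = integer(), rank = integer(),
                          tis_score = numeric(), tis_positive = logical())
  }
  out
}
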