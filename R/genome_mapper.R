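#' BED intervals for noncanonical peptides
#'
#' Emits one BED6 record per (peptide, 3FT hit): the genomic interval of the
#' matched residue window, named by the peptide sequence, score 0, with the
#' segment's strand. Output is deterministically sorted by
#' (chrom, start, name). Coordinates are 0-based half-open, BED-native.
#'
#' Besides the six BED columns the tibble carries gene_id and frame of the
#' matched segment, which downstream feature annotation and upstream
#' start-codon scanning rely on.
#'
#' @param classified An `ncmap_classification` from [classify_peptides()];
#'   only noncanonical rows are emitted.
#' @param threeft The `threeft_index` the classification was run against.
#' @return Tibble (chrom, start, end, name, score, strand, gene_id, frame).
#' @export
peptides_to_bed <- function(classified, threeft) {
  nc <- classified[classified$category == "noncanonical", , drop = FALSE]
  rows <- purrr::map2(nc$sequence, nc$threeft_hits, function(seq, hits) {
    if (nrow(hits) == 0L) return(NULL)
    purrr::map2(hits$segment, hits$aa_offset, function(si, off) {
      seg <- threeft[si, ]
      iv <- segment_to_genomic(seg, off, nchar(seq))
      dplyr::mutate(iv, name = seq, score = 0L,
                    gene_id = seg$gene_id, frame = seg$frame)
    })
  })
  out <- dplyr::bind_rows(purrr::list_flatten(rows))
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = integer(), strand = character(),
                          gene_id = character(), frame = integer()))
  }
  out %>%
    dplyr::select("chrom", "start", "end", "name", "score", "strand",
                  "gene_id", "frame") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$name)
}

#' Write BED6 records to a file
#'
#' @param bed Tibble with columns chrom, start, end, name, score, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed[, c("chrom", "start", "end", "name", "score", "strand")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a tibble
#'
#' @param path BED path (3 to 6 columns).
#' @return Tibble (chrom, start, end, name, score, strand).
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(tbl) <- cols[seq_len(ncol(tbl))]
  if (!"name" %in% names(tbl)) tbl$name <- paste0("iv", seq_len(nrow(tbl)))
  if (!"score" %in% names(tbl)) tbl$score <- 0L
  if (!"strand" %in% names(tbl)) tbl$strand <- "+"
  tbl
}

# first codon-grid class (genomic position mod 3 of codon starts) of the
# CDS within each CDS exon of a transcript, in transcription order
cds_grid_classes <- function(cds_tx) {
  cds_tx <- dplyr::arrange(cds_tx, .data$start)
  minus <- cds_tx$strand[1] == "-"
  ord <- if (minus) rev(seq_len(nrow(cds_tx))) else seq_len(nrow(cds_tx))
  cum <- 0L
  grid <- integer(nrow(cds_tx))
  for (i in ord) {
    need <- (3L - cum %% 3L) %% 3L  # bases completing the junction codon
    first_start <- if (minus) cds_tx$end[i] - 1L - need else cds_tx$start[i] + need
    grid[i] <- first_start %% 3L
    cum <- cum + (cds_tx$end[i] - cds_tx$start[i])
  }
  cds_tx$grid <- grid
  cds_tx
}

#' Annotate a peptide interval by gene feature
#'
#' Labels an interval with the gene features it intersects, per transcript
#' of its host gene(s): `intronic` if it overlaps an intron,
#' `five_prime_utr` / `three_prime_utr` if it overlaps the region of the
#' transcript 5' / 3' of the CDS extent (derived from CDS when UTR features
#' are absent, strand-aware), and `exonic_alt_frame` if it overlaps CDS in
#' a codon frame different from the reading frame of the canonical CDS at
#' that position. Labels are not mutually exclusive: an interval spanning a
#' UTR/CDS junction receives both labels, and the union over transcripts is
#' reported with supporting transcript ids.
#'
#' @param interval One-row tibble or list (chrom, start, end, strand), e.g.
#'   a row of [peptides_to_bed()] output. A `frame` or codon-grid is taken
#'   from the interval itself: its 5' end defines the peptide's codon grid.
#' @param ref A `reference_model`.
#' @return Tibble (label, transcript_id), zero rows when the interval lies
#'   outside all genes.
#' @export
annotate_features <- function(interval, ref) {
  empty <- tibble::tibble(label = character(), transcript_id = character())
  if (!interval$chrom %in% names(ref$chromosomes)) {
    abort(paste0("unknown chromosome: ", interval$chrom))
  }
  hosts <- ref$genes[ref$genes$chrom == interval$chrom &
                       ref$genes$strand == interval$strand &
                       ref$genes$start < interval$end &
                       ref$genes$end > interval$start, ]
  if (nrow(hosts) == 0L) return(empty)
  minus <- interval$strand == "-"
  pep_grid <- if (minus) (interval$end - 1L) %% 3L else interval$start %% 3L

  labels <- list()
  add <- function(label, tx) {
    labels[[length(labels) + 1L]] <<- tibble::tibble(label = label,
                                                    transcript_id = tx)
  }
  txs <- ref$transcripts[ref$transcripts$gene_id %in% hosts$gene_id, ]
  introns <- transcript_introns(ref)
  for (tx in txs$transcript_id) {
    ex <- ref$exons[ref$exons$transcript_id == tx, ]
    intr <- introns[introns$transcript_id == tx, ]
    if (nrow(intr) > 0L &&
        any(intr$start < interval$end & intr$end > interval$start)) {
      add("intronic", tx)
    }
    cds_tx <- ref$cds[ref$cds$transcript_id == tx, ]
    if (nrow(cds_tx) == 0L) next
    cds_lo <- min(cds_tx$start); cds_hi <- max(cds_tx$end)
    # exonic regions outside the CDS extent are UTR; 5' vs 3' by strand
    utr_lo <- ex[ex$start < cds_lo, ]; utr_lo$end <- pmin(utr_lo$end, cds_lo)
    utr_hi <- ex[ex$end > cds_hi, ]; utr_hi$start <- pmax(utr_hi$start, cds_hi)
    five <- if (minus) utr_hi else utr_lo
    three <- if (minus) utr_lo else utr_hi
    if (nrow(five) > 0L &&
        any(five$start < interval$end & five$end > interval$start)) {
      add("five_prime_utr", tx)
    }
    if (nrow(three) > 0L &&
        any(three$start < interval$end & three$end > interval$start)) {
      add("three_prime_utr", tx)
    }
    cds_tx <- cds_grid_classes(cds_tx)
    hit_cds <- cds_tx[cds_tx$start < interval$end & cds_tx$end > interval$start, ]
    if (nrow(hit_cds) > 0L && any(hit_cds$grid != pep_grid)) {
      add("exonic_alt_frame", tx)
    }
  }
  if (length(labels) == 0L) return(empty)
  dplyr::distinct(dplyr::bind_rows(labels))
}

#' Feature annotation table for a BED set
#'
#' Applies [annotate_features()] to every row of a peptide BED tibble and
#' returns one row per (peptide interval, label, transcript).
#'
#' @param bed Output of [peptides_to_bed()] (or any tibble with chrom,
#'   start, end, name, strand).
#' @param ref A `reference_model`.
#' @return Tibble of class `ncmap_features`:
#'   (name, chrom, start, end, strand, label, transcript_id).
#' @export
annotate_bed_features <- function(bed, ref) {
  rows <- purrr::map(seq_len(nrow(bed)), function(i) {
    iv <- bed[i, ]
    ann <- annotate_features(iv, ref)
    if (nrow(ann) == 0L) return(NULL)
    dplyr::mutate(ann, name = iv$name, chrom = iv$chrom, start = iv$start,
                  end = iv$end, strand = iv$strand, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(name = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), label = character(),
                          transcript_id = character())
  }
  class(out) <- c("ncmap_features", class(out))
  out
}
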