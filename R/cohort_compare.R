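as_granges <- function(tbl, ignore_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = if (ignore_strand) "*" else tbl$strand
  )
}

#' Genomic-coordinate overlap of two peptide sets
#'
#' Compares two sets of peptide genomic intervals: a peptide is *shared*
#' when it overlaps at least one peptide of the other set by at least
#' `min_overlap` nucleotides (on the same strand unless
#' `ignore_strand = TRUE`), and *exclusive* otherwise. Overlap length is
#' computed on 0-based half-open intervals. Counts are per peptide, not per
#' merged cluster, so partially matching sequences (longer, shorter,
#' shifted) still pair up.
#'
#' @param set_a,set_b Tibbles with columns chrom, start, end, name, strand
#'   (e.g. from [peptides_to_bed()] or [read_bed()]).
#' @param min_overlap Minimum overlap in nucleotides (default 21 nt = 7
#'   amino acids, the shortest peptide considered).
#' @param ignore_strand Overlap regardless of strand.
#' @return An object of class `overlap_report`: list with `totals`,
#'   `shared`, `exclusive` (named vectors for sets "a" and "b") and
#'   `links`, a tibble of pairwise links (name_a, name_b, overlap_nt).
#'   [generics::tidy()] returns the links, [generics::glance()] the counts.
#' @export
overlap_sets <- function(set_a, set_b, min_overlap = 21L,
                         ignore_strand = FALSE) {
  gr_a <- as_granges(set_a, ignore_strand)
  gr_b <- as_granges(set_b, ignore_strand)
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = min_overlap,
                                      ignore.strand = ignore_strand)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_a)[qh], IRanges::ranges(gr_b)[sh]))
  links <- tibble::tibble(
    name_a = set_a$name[qh], name_b = set_b$name[sh],
    overlap_nt = as.integer(ov)
  ) %>%
    dplyr::arrange(.data$name_a, .data$name_b)

  shared_a <- length(unique(qh)); shared_b <- length(unique(sh))
  report <- structure(
    list(
      totals = c(a = nrow(set_a), b = nrow(set_b)),
      shared = c(a = shared_a, b = shared_b),
      exclusive = c(a = nrow(set_a) - shared_a, b = nrow(set_b) - shared_b),
      links = links,
      min_overlap = min_overlap
    ),
    class = "overlap_report"
  )
  report
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> min_overlap = %d nt\n", x$min_overlap))
  cat(sprintf("  set a: %d total, %d shared, %d exclusive\n",
              x$totals["a"], x$shared["a"], x$exclusive["a"]))
  cat(sprintf("  set b: %d total, %d shared, %d exclusive\n",
              x$totals["b"], x$shared["b"], x$exclusive["b"]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.overlap_report <- function(x, ...) x$links

#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(
    total_a = unname(x$totals["a"]), total_b = unname(x$totals["b"]),
    shared_a = unname(x$shared["a"]), shared_b = unname(x$shared["b"]),
    exclusive_a = unname(x$exclusive["a"]),
    exclusive_b = unname(x$exclusive["b"]),
    min_overlap = x$min_overlap
  )
}

#' Multi-set overlap report
#'
#' Extends [overlap_sets()] to more than two sets: for each set, a peptide
#' is shared under `"any"` semantics when it overlaps a peptide of at least
#' one other set, and under `"all"` semantics when it overlaps peptides of
#' every other set.
#'
#' @param sets Named list of interval tibbles.
#' @param min_overlap Minimum overlap in nucleotides.
#' @param ignore_strand Overlap regardless of strand.
#' @return Tibble (set, total, shared_any, shared_all, exclusive).
#' @export
overlap_multi <- function(sets, min_overlap = 21L, ignore_strand = FALSE) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  out <- purrr::imap(sets, function(this, nm) {
    others <- sets[setdiff(names(sets), nm)]
    per_other <- purrr::map(others, function(other) {
      r <- overlap_sets(this, other, min_overlap, ignore_strand)
      unique(r$links$name_a)
    })
    any_shared <- unique(unlist(per_other))
    all_shared <- purrr::reduce(per_other, intersect)
    tibble::tibble(set = nm, total = nrow(this),
                   shared_any = length(any_shared),
                   shared_all = length(all_shared),
                   exclusive = nrow(this) - length(any_shared))
  })
  dplyr::bind_rows(out)
}
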