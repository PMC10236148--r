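#' Positionwise mismatch profile of two equal-length peptides
#'
#' Compares two amino-acid strings position by position. Differences where
#' the two residues are the isobaric pair I/L (indistinguishable by tandem
#' MS) are counted separately (`li`) from all other differences (`hard`).
#'
#' @param peptide,window Equal-length uppercase amino-acid strings.
#' @return A list with integer fields `hard` and `li`.
#' @export
mismatch_profile <- function(peptide, window) {
  if (nchar(peptide) != nchar(window)) {
    abort("mismatch_profile() requires equal-length sequences")
  }
  a <- strsplit(peptide, "", fixed = TRUE)[[1]]
  b <- strsplit(window, "", fixed = TRUE)[[1]]
  diff <- a != b
  li <- diff & ((a == "I" & b == "L") | (a == "L" & b == "I"))
  list(hard = sum(diff & !li), li = sum(li))
}

# integer-coded proteome for the vectorised window scan
encode_aa <- function(s) utf8ToInt(s)

#' Minimum substitution distance of a peptide to a proteome
#'
#' Exhaustive Hamming window scan: the peptide is compared against every
#' length-matched window of every protein and the best profile is returned,
#' minimising lexicographically over `(hard + li, hard)`. All windows
#' achieving the minimum are reported. Substitution-only scanning is exact
#' and deterministic; insertions/deletions are out of contract.
#'
#' @param peptide Uppercase amino-acid string.
#' @param proteome Named character vector of protein sequences (names are
#'   protein ids), or a tibble with columns `protein_id` and `seq`.
#' @return A list with fields `hard`, `li` and `hits`, a tibble
#'   (protein_id, offset) of 0-based window offsets achieving the minimum.
#'   A peptide longer than every protein yields
#'   `hard = nchar(peptide), li = 0` with no hits.
#' @export
min_proteome_distance <- function(peptide, proteome) {
  proteome <- as_proteome(proteome)
  if (length(proteome) == 0L) abort("proteome is empty")
  k <- nchar(peptide)
  q <- encode_aa(peptide)
  iI <- utf8ToInt("I"); iL <- utf8ToInt("L")
  q_il <- q == iI | q == iL

  best_hard <- k; best_li <- 0L; best_total <- k + 1L
  hits <- list()
  for (pid in names(proteome)) {
    p <- encode_aa(proteome[[pid]])
    n_win <- length(p) - k + 1L
    if (n_win < 1L) next
    hard <- integer(n_win)
    li <- integer(n_win)
    for (j in seq_len(k)) {
      w <- p[j:(j + n_win - 1L)]
      diff <- w != q[j]
      if (q_il[j]) {
        isli <- diff & (w == iI | w == iL)
        li <- li + isli
        hard <- hard + (diff & !isli)
      } else {
        hard <- hard + diff
      }
    }
    total <- hard + li
    m <- min(total)
    if (m > best_total) next
    cand <- which(total == m)
    # among equal totals prefer fewer hard mismatches
    h <- min(hard[cand])
    cand <- cand[hard[cand] == h]
    if (m < best_total || (m == best_total && h < best_hard)) {
      best_total <- m; best_hard <- h; best_li <- m - h
      hits <- list()
    }
    if (m == best_total && h == best_hard) {
      hits[[length(hits) + 1L]] <- tibble::tibble(protein_id = pid,
                                                 offset = cand - 1L)
    }
  }
  if (length(hits) == 0L) {
    return(list(hard = k, li = 0L,
                hits = tibble::tibble(protein_id = character(), offset = integer())))
  }
  list(hard = as.integer(best_hard), li = as.integer(best_li),
       hits = dplyr::bind_rows(hits))
}

as_proteome <- function(proteome) {
  if (is.data.frame(proteome)) {
    out <- proteome$seq
    names(out) <- proteome$protein_id
    return(out)
  }
  if (is.null(names(proteome))) {
    names(proteome) <- paste0("protein_", seq_along(proteome))
  }
  proteome
}

#' Exact 3FT substring hits of a peptide
#'
#' Finds every occurrence of `peptide` as an exact substring of a 3FT
#' segment. I and L are distinguished by default; with
#' `xle_tolerant = TRUE` a single I/L interchange is tolerated (used only
#' when harmonising peptide sets from other studies).
#'
#' @param peptide Uppercase amino-acid string.
#' @param threeft A `threeft_index` from [build_3ft()].
#' @param xle_tolerant Allow at most one I/L mismatch.
#' @return Tibble (segment, aa_offset): the row index of the segment in
#'   `threeft` and the 0-based residue offset of the match.
#' @export
threeft_match <- function(peptide, threeft, xle_tolerant = FALSE) {
  empty <- tibble::tibble(segment = integer(), aa_offset = integer())
  if (nrow(threeft) == 0L) return(empty)
  subject <- Biostrings::AAStringSet(threeft$aa_seq)
  max_mm <- if (xle_tolerant) 1L else 0L
  m <- Biostrings::vmatchPattern(peptide, subject, max.mismatch = max_mm,
                                 fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  rows <- purrr::imap(starts, function(st, i) {
    if (is.null(st) || length(st) == 0L) return(NULL)
    tibble::tibble(segment = i, aa_offset = st - 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  if (xle_tolerant) {
    keep <- purrr::map2_lgl(out$segment, out$aa_offset, function(si, off) {
      win <- substr(threeft$aa_seq[si], off + 1L, off + nchar(peptide))
      prof <- mismatch_profile(peptide, win)
      prof$hard == 0L && prof$li <= 1L
    })
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Sequential canonical / noncanonical / unmapped classification
#'
#' Applies the sequential annotation rule to each peptide:
#' 1. *canonical* if its best proteome profile has `hard == 0` and
#'    `li <= 1` (a perfect match up to one isobaric I/L interchange);
#' 2. otherwise *noncanonical* if it occurs verbatim in the 3FT index
#'    (I and L distinguished) **and** its minimum proteome distance
#'    (`hard + li`) is at least `min_mismatch`;
#' 3. otherwise *unmapped*. Peptides with a 3FT hit but 1-2 total
#'    proteome mismatches fall in this buffer zone by design.
#'
#' @param peptides Character vector of sequences, or a tibble with a
#'   `sequence` column (extra columns such as `sample_id`, `score` are
#'   carried through).
#' @param proteome Named character vector or tibble (`protein_id`, `seq`).
#' @param threeft A `threeft_index` from [build_3ft()].
#' @param min_mismatch Minimum total proteome mismatches required before a
#'   3FT-matching peptide is called noncanonical (default 3).
#' @param min_len,max_len Length band; peptides outside it are kept but a
#'   warning is raised.
#' @param xle_tolerant_3ft Tolerate one I/L mismatch in the 3FT match
#'   (comparison mode for external peptide sets; off by default).
#' @return A tibble of class `ncmap_classification` with one row per
#'   peptide: sequence, category, hard, li, proteome_hits and threeft_hits
#'   (list columns).
#' @export
classify_peptides <- function(peptides, proteome, threeft,
                              min_mismatch = 3L, min_len = 7L, max_len = 25L,
                              xle_tolerant_3ft = FALSE) {
  tbl <- if (is.data.frame(peptides)) peptides else tibble::tibble(sequence = peptides)
  if (!"sequence" %in% names(tbl)) abort("peptide table needs a `sequence` column")
  lens <- nchar(tbl$sequence)
  if (any(lens < min_len | lens > max_len)) {
    warn(sprintf("%d peptide(s) outside the %d-%d residue band",
                 sum(lens < min_len | lens > max_len), min_len, max_len))
  }

  res <- purrr::map(tbl$sequence, function(seq) {
    prof <- min_proteome_distance(seq, proteome)
    if (prof$hard == 0L && prof$li <= 1L) {
      return(list(category = "canonical", hard = prof$hard, li = prof$li,
                  proteome_hits = prof$hits,
                  threeft_hits = tibble::tibble(segment = integer(),
                                                aa_offset = integer())))
    }
    hits3 <- threeft_match(seq, threeft, xle_tolerant = xle_tolerant_3ft)
    if (nrow(hits3) > 0L && prof$hard + prof$li >= min_mismatch) {
      return(list(category = "noncanonical", hard = prof$hard, li = prof$li,
                  proteome_hits = prof$hits, threeft_hits = hits3))
    }
    list(category = "unmapped", hard = prof$hard, li = prof$li,
         proteome_hits = prof$hits, threeft_hits = hits3)
  })

  out <- dplyr::mutate(
    tbl,
    category = purrr::map_chr(res, "category"),
    hard = purrr::map_int(res, ~ as.integer(.x$hard)),
    li = purrr::map_int(res, ~ as.integer(.x$li)),
    proteome_hits = purrr::map(res, "proteome_hits"),
    threeft_hits = purrr::map(res, "threeft_hits")
  )
  class(out) <- c("ncmap_classification", class(out))
  out
}

#' Export the second-round search database
#'
#' Writes a FASTA containing the canonical proteome followed by one entry
#' per unique noncanonical peptide, in deterministic order (proteome order,
#' then peptides lexicographically). Peptide headers are
#' `>NC|{sha1-prefix}|{length}`.
#'
#' @param classified An `ncmap_classification` (only noncanonical rows are
#'   used), or a character vector of noncanonical peptide sequences.
#' @param proteome Named character vector or tibble (`protein_id`, `seq`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_second_round_db <- function(classified, proteome, path) {
  peps <- if (is.data.frame(classified)) {
    classified$sequence[classified$category == "noncanonical"]
  } else {
    classified
  }
  peps <- sort(unique(peps))
  proteome <- as_proteome(proteome)
  headers <- c(names(proteome),
               sprintf("NC|%s|%d",
                       substr(purrr::map_chr(peps, digest::digest,
                                             algo = "sha1", serialize = FALSE),
                              1L, 10L),
                       nchar(peps)))
  set <- Biostrings::AAStringSet(c(unname(proteome), peps))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
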