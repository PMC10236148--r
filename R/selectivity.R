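#' Per-tissue expression percentiles from sample-level TPM
#'
#' Collapses sample-level TPM values to one value per (gene, tissue): the
#' `q`th percentile over all samples of that tissue, a deliberately
#' upper-end summary so that a gene passing a downstream cutoff is below it
#' in essentially every individual. Empty cells are reported as missing,
#' never as zero.
#'
#' @param tpm Tibble (gene_id, tissue, tpm), one row per sample measurement
#'   (extra columns ignored).
#' @param q Percentile, in percent (default 90).
#' @param method `"linear"` (interpolated, `stats::quantile` type 7, the
#'   default) or `"nearest"` (nearest-rank, type 1).
#' @return Tibble (gene_id, tissue, tpm_q) with one row per non-empty cell.
#' @export
tissue_percentile <- function(tpm, q = 90, method = c("linear", "nearest")) {
  method <- match.arg(method)
  type <- if (method == "linear") 7L else 1L
  if (any(tpm$tpm < 0, na.rm = TRUE)) abort("negative TPM value")
  tpm %>%
    dplyr::filter(!is.na(.data$tpm)) %>%
    dplyr::group_by(.data$gene_id, .data$tissue) %>%
    dplyr::summarise(
      tpm_q = stats::quantile(.data$tpm, probs = q / 100, type = .env$type,
                              names = FALSE),
      .groups = "drop"
    )
}

#' Three-step cancer-selectivity triage
#'
#' Labels each peptide by the first failing step, in fixed order:
#' 1. peptides detected in the panel of normal immunopeptidomes are
#'    `non_cancer_selective_ms`;
#' 2. peptides with any parent gene whose expression reaches `tpm_cutoff`
#'    in any non-excluded tissue are `expressed_above_cutoff`;
#' 3. peptides with any parent gene showing protein expression in at least
#'    one healthy tissue are `protein_expressed`;
#' peptides passing all three steps are `cancer_selective`. With multiple
#' parent genes the test is a conservative AND: every parent gene must pass
#' steps 2 and 3.
#'
#' @param peptide_genes Tibble (peptide, gene_id) linking each peptide to
#'   its parent gene(s).
#' @param panel Character vector of peptide sequences seen in healthy
#'   immunopeptidome samples (exact sequence membership).
#' @param expr Tibble (gene_id, tissue, tpm_q) of per-tissue expression
#'   summaries, e.g. from [tissue_percentile()].
#' @param protein_evidence Tibble (gene_id, n_tissues) counting healthy
#'   tissues with protein expression for the gene (an optional
#'   `denominator` column, default 56, is carried into the evidence).
#' @param tpm_cutoff Expression cutoff in TPM (default 1).
#' @param excluded_tissues Tissues ignored in step 2 (default `"testis"`,
#'   an immune-privileged site; the same exclusion is assumed already
#'   applied to the protein-evidence counts).
#' @param missing_gene `"error"` (default) to stop when a parent gene is
#'   absent from `expr` or `protein_evidence`; `"fail"` to treat a missing
#'   gene as failing the step conservatively.
#' @return Tibble of class `ncmap_selectivity`: (peptide, label, in_panel,
#'   max_tpm, max_protein_tissues), one row per peptide.
#' @export
classify_selectivity <- function(peptide_genes, panel, expr, protein_evidence,
                                 tpm_cutoff = 1, excluded_tissues = "testis",
                                 missing_gene = c("error", "fail")) {
  missing_gene <- match.arg(missing_gene)
  stopifnot(all(c("peptide", "gene_id") %in% names(peptide_genes)))
  expr_use <- dplyr::filter(expr, !(.data$tissue %in% excluded_tissues))

  out <- peptide_genes %>%
    dplyr::distinct(.data$peptide, .data$gene_id) %>%
    dplyr::group_by(.data$peptide) %>%
    dplyr::summarise(genes = list(.data$gene_id), .groups = "drop")

  labels <- purrr::map(out$genes, function(genes) {
    e <- expr_use[expr_use$gene_id %in% genes, ]
    p <- protein_evidence[protein_evidence$gene_id %in% genes, ]
    if (missing_gene == "error") {
      absent <- setdiff(genes, unique(expr$gene_id))
      if (length(absent) > 0L) {
        abort(paste0("gene absent from expression table: ", absent[1]))
      }
      absent_p <- setdiff(genes, unique(protein_evidence$gene_id))
      if (length(absent_p) > 0L) {
        abort(paste0("gene absent from protein-evidence table: ", absent_p[1]))
      }
    } else {
      if (!all(genes %in% unique(expr$gene_id))) {
        return(list(max_tpm = Inf, max_prot = NA_integer_))
      }
      if (!all(genes %in% unique(protein_evidence$gene_id))) {
        return(list(max_tpm = suppressWarnings(max(e$tpm_q, 0)),
                    max_prot = .Machine$integer.max))
      }
    }
    list(max_tpm = if (nrow(e) > 0L) max(e$tpm_q) else 0,
         max_prot = if (nrow(p) > 0L) max(p$n_tissues) else 0L)
  })

  res <- dplyr::mutate(
    out,
    in_panel = .data$peptide %in% panel,
    max_tpm = purrr::map_dbl(labels, "max_tpm"),
    max_protein_tissues = purrr::map_int(labels, ~ as.integer(.x$max_prot)),
    label = dplyr::case_when(
      .data$in_panel ~ "non_cancer_selective_ms",
      .data$max_tpm >= tpm_cutoff ~ "expressed_above_cutoff",
      .data$max_protein_tissues > 0L ~ "protein_expressed",
      TRUE ~ "cancer_selective"
    )
  ) %>%
    dplyr::select("peptide", "label", "in_panel", "max_tpm",
                  "max_protein_tissues")
  class(res) <- c("ncmap_selectivity", class(res))
  res
}

#' Binarise an EL-rank table into a binding matrix
#'
#' Entries with eluted-ligand percentile rank at or below `threshold`
#' (strong binders) become 1, all others 0.
#'
#' @param el_ranks Tibble (allele, peptide, el_rank) with ranks in percent,
#'   or an allele x peptide numeric matrix.
#' @param threshold Strong-binder rank cutoff in percent (default 0.5,
#'   inclusive).
#' @return Binary allele x peptide matrix.
#' @export
build_binding_matrix <- function(el_ranks, threshold = 0.5) {
  if (is.matrix(el_ranks)) {
    m <- el_ranks
  } else {
    wide <- tidyr::pivot_wider(el_ranks, names_from = "peptide",
                               values_from = "el_rank")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$allele
  }
  if (any(m < 0, na.rm = TRUE)) abort("negative EL rank")
  out <- (m <= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Pairwise cosine distance between allele binding profiles
#'
#' `d(a, b) = 1 - (a . b) / (||a|| ||b||)` over the rows of a binding
#' matrix; symmetric with a zero diagonal.
#'
#' @param bm Binary allele x peptide matrix from [build_binding_matrix()].
#' @return Symmetric allele x allele distance matrix.
#' @export
allele_distance <- function(bm) {
  norms <- sqrt(rowSums(bm^2))
  zero <- norms == 0
  if (any(zero)) {
    abort(paste0("all-zero binding vector for allele: ",
                 rownames(bm)[zero][1]))
  }
  sim <- (bm %*% t(bm)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0  # numeric guard
  diag(d) <- 0
  d
}
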