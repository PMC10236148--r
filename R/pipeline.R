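#' Read a peptide list
#'
#' Accepts either plain text (one sequence per line) or TSV with a
#' `sequence` column and optional `sample_id` / `score` columns.
#'
#' @param path Input path.
#' @return Tibble with at least a `sequence` column.
#' @export
read_peptides <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (stringr::str_detect(first, "\t") || first == "sequence") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"sequence" %in% names(tbl)) {
      abort("peptide TSV needs a `sequence` column")
    }
  } else {
    tbl <- tibble::tibble(sequence = readr::read_lines(path))
    tbl <- tbl[nchar(tbl$sequence) > 0L, ]
  }
  dplyr::mutate(tbl, sequence = toupper(.data$sequence))
}

#' Read a proteome FASTA into a named vector
#'
#' Decoy (`rev_`/`REV_` prefixed) and contaminant (`CON_`/`cont_`) entries,
#' which exist only for MS FDR control, are dropped so they never enter the
#' mismatch-distance computation.
#'
#' @param path FASTA path.
#' @param drop_decoys Drop decoy/contaminant entries (default TRUE).
#' @return Named character vector of protein sequences.
#' @export
read_proteome_fasta <- function(path, drop_decoys = TRUE) {
  set <- Biostrings::readAAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  out <- stats::setNames(as.character(set), names(set))
  if (drop_decoys) {
    out <- out[!stringr::str_detect(names(out),
                                    stringr::regex("^(rev_|con_|cont_)",
                                                   ignore_case = TRUE))]
  }
  out
}

#' Run the full annotation pipeline
#'
#' Chains the stages in their fixed order: build the 3FT search space,
#' classify peptides, map noncanonical peptides to BED, annotate gene
#' features, scan upstream ORFs, test intron-retention frames, match
#' frameshift mutants (when a VCF is given) and triage cancer selectivity
#' (when expression tables are given). Stage outputs are written into
#' `out_dir` as TSV/BED/FASTA plus a JSON summary of per-stage counts; the
#' run is a pure function of its inputs and configuration.
#'
#' @param config A named list with paths and parameters:
#'   `genome`, `gtf`, `proteome`, `peptides` (required paths);
#'   `vcf`, `expression`, `protein_evidence`, `panel` (optional paths);
#'   parameters `min_mismatch` (3), `min_overlap` (21), `tpm_cutoff` (1),
#'   `min_len` (7), `max_len` (25), `excluded_tissues` ("testis").
#' @param out_dir Output directory.
#' @return Invisibly, a list with the stage results and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  required <- c("genome", "gtf", "proteome", "peptides")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L) {
    abort(paste0("config is missing required path(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (key in intersect(names(config),
                        c(required, "vcf", "expression", "protein_evidence",
                          "panel"))) {
    if (!file.exists(config[[key]])) {
      abort(paste0("config path does not exist: ", key, " = ", config[[key]]))
    }
  }
  p <- function(name, default) config[[name]] %||% default
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- load_reference(config$genome, config$gtf)
  proteome <- read_proteome_fasta(config$proteome)
  peptides <- read_peptides(config$peptides)

  threeft <- build_3ft(ref, min_len = p("min_len", 7L))
  write_3ft_fasta(threeft, file.path(out_dir, "threeft.fasta"))

  classified <- classify_peptides(
    peptides, proteome, threeft,
    min_mismatch = p("min_mismatch", 3L),
    min_len = p("min_len", 7L), max_len = p("max_len", 25L))
  readr::write_tsv(
    dplyr::select(classified, -"proteome_hits", -"threeft_hits"),
    file.path(out_dir, "classification.tsv"))
  export_second_round_db(classified, proteome,
                         file.path(out_dir, "second_round_db.fasta"))

  bed <- peptides_to_bed(classified, threeft)
  write_bed(bed, file.path(out_dir, "noncanonical.bed"))

  features <- annotate_bed_features(bed, ref)
  readr::write_tsv(features, file.path(out_dir, "features.tsv"))

  orf <- orf_scan(bed, ref)
  readr::write_tsv(orf, file.path(out_dir, "orf_scan.tsv"))

  ir <- ir_check(bed, ref)
  readr::write_tsv(ir, file.path(out_dir, "ir_check.tsv"))

  fs_hits <- NULL
  if (!is.null(config$vcf)) {
    variants <- frameshift_variants(ref, read_frameshift_vcf(config$vcf))
    mutants <- build_mutant_proteins(ref, variants)
    fs_hits <- match_frameshift(peptides, mutants)
    readr::write_tsv(fs_hits, file.path(out_dir, "frameshift_hits.tsv"))
  }

  selectivity <- NULL
  if (!is.null(config$expression) && !is.null(config$protein_evidence)) {
    expr <- readr::read_tsv(config$expression, show_col_types = FALSE)
    q90 <- tissue_percentile(expr, q = 90)
    prot <- readr::read_tsv(config$protein_evidence, show_col_types = FALSE)
    panel <- if (!is.null(config$panel)) {
      readr::read_lines(config$panel)
    } else {
      character()
    }
    nc_genes <- bed %>%
      dplyr::distinct(peptide = .data$name, gene_id = .data$gene_id)
    selectivity <- classify_selectivity(
      nc_genes, panel, q90, prot,
      tpm_cutoff = p("tpm_cutoff", 1),
      excluded_tissues = p("excluded_tissues", "testis"))
    readr::write_tsv(selectivity, file.path(out_dir, "selectivity.tsv"))
  }

  summary <- list(
    n_peptides = nrow(peptides),
    n_3ft_segments = nrow(threeft),
    n_canonical = sum(classified$category == "canonical"),
    n_noncanonical = sum(classified$category == "noncanonical"),
    n_unmapped = sum(classified$category == "unmapped"),
    n_bed_records = nrow(bed),
    n_feature_labels = nrow(features),
    n_orf_hits = nrow(orf),
    n_ir_records = nrow(ir),
    n_frameshift_hits = if (is.null(fs_hits)) NA_integer_ else nrow(fs_hits),
    n_cancer_selective = if (is.null(selectivity)) NA_integer_ else
      sum(selectivity$label == "cancer_selective"),
    skipped = c(if (is.null(fs_hits)) "frameshift" else NULL,
                if (is.null(selectivity)) "selectivity" else NULL)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(ref = ref, threeft = threeft, classified = classified,
                 bed = bed, features = features, orf = orf, ir = ir,
                 frameshift = fs_hits, selectivity = selectivity,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
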