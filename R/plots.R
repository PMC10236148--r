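#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the category breakdown of a classification
#'
#' Bar chart of canonical / noncanonical / unmapped counts.
#'
#' @param object An `ncmap_classification` from [classify_peptides()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ncmap_classification <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$category)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "peptides",
                  title = "Peptide classification") +
    ggplot2::theme_minimal()
}

#' Plot the gene-feature annotation breakdown
#'
#' Bar chart of the fraction of distinct peptides carrying each feature
#' label; labels are not mutually exclusive, so fractions need not sum
#' to one.
#'
#' @param object An `ncmap_features` tibble from [annotate_bed_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ncmap_features <- function(object, ...) {
  tbl <- tibble::as_tibble(object) %>%
    dplyr::distinct(.data$name, .data$label) %>%
    dplyr::count(.data$label) %>%
    dplyr::mutate(fraction = .data$n / dplyr::n_distinct(object$name))
  ggplot2::ggplot(tbl, ggplot2::aes(x = stats::reorder(.data$label,
                                                       -.data$fraction),
                                    y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of noncanonical peptides",
                  title = "Gene-feature annotation") +
    ggplot2::theme_minimal()
}

#' Plot a de novo calibration curve
#'
#' Accuracy over the retained set as a function of the score threshold,
#' with the target accuracy and the chosen operating point marked.
#'
#' @param object A `denovo_calibration` from [calibrate_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.denovo_calibration <- function(object, ...) {
  gg <- ggplot2::ggplot(object$curve,
                        ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$target, linetype = "dashed") +
    ggplot2::labs(x = "score threshold", y = "accuracy of retained set",
                  title = "De novo score calibration") +
    ggplot2::theme_minimal()
  if (object$attainable) {
    gg <- gg + ggplot2::annotate("point", x = object$threshold,
                                 y = object$achieved_accuracy,
                                 colour = "red", size = 2)
  }
  gg
}

#' Plot shared and exclusive counts of an overlap report
#'
#' @param object An `overlap_report` from [overlap_sets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_report <- function(object, ...) {
  tbl <- tibble::tibble(
    set = rep(c("a", "b"), each = 2L),
    status = rep(c("shared", "exclusive"), 2L),
    n = c(object$shared["a"], object$exclusive["a"],
          object$shared["b"], object$exclusive["b"])
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$set, y = .data$n,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "peptide set", y = "peptides",
                  title = sprintf("Genomic overlap (>= %d nt)",
                                  object$min_overlap)) +
    ggplot2::theme_minimal()
}

#' Plot the selectivity triage outcome
#'
#' @param object An `ncmap_selectivity` from [classify_selectivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ncmap_selectivity <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$label)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$label,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "peptides",
                  title = "Cancer-selectivity triage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
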