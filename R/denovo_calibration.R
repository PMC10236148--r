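#' Whole-sequence equivalence under I/L isobarity
#'
#' Two peptide sequences are equivalent when they have equal length and
#' agree at every position with isoleucine and leucine interchangeable
#' (the pair is isobaric and indistinguishable by standard tandem MS).
#' Inline PTM annotations (parenthesised or bracketed mass tags,
#' `+12.34`-style deltas) are stripped before comparison: calibration
#' concerns backbone sequence identity.
#'
#' @param pred,truth Character vectors of peptide sequences (recycled to a
#'   common length).
#' @return Logical vector.
#' @export
sequences_equivalent <- function(pred, truth) {
  norm <- function(x) {
    x <- stringr::str_remove_all(x, "\\([^)]*\\)|\\[[^\\]]*\\]|[+-]?\\d+(\\.\\d+)?")
    chartr("I", "L", toupper(x))
  }
  norm(pred) == norm(truth)
}

#' Calibrate a de novo score threshold to a target accuracy
#'
#' Chooses, among the distinct observed scores, the minimum threshold `t`
#' such that whole-sequence accuracy over the retained set
#' `{score >= t}` reaches `target`; the minimum is taken so ties break
#' toward the largest retained set. When even the top-scored subset misses
#' the target, the result is flagged unattainable (`threshold = Inf`,
#' nothing retained).
#'
#' @param preds Tibble (predicted, truth, score), one row per validation
#'   prediction; `correct` may be supplied directly instead of
#'   `predicted`/`truth`.
#' @param target Target accuracy as a fraction (default 0.90).
#' @return Object of class `denovo_calibration`: list with `threshold`,
#'   `achieved_accuracy`, `retained_fraction`, `attainable`, `target`, and
#'   `curve`, the per-candidate-threshold tibble. [generics::tidy()]
#'   returns the curve, [generics::glance()] the chosen operating point.
#' @export
calibrate_threshold <- function(preds, target = 0.90) {
  if (nrow(preds) == 0L) abort("no predictions to calibrate on")
  correct <- if ("correct" %in% names(preds)) {
    as.logical(preds$correct)
  } else {
    sequences_equivalent(preds$predicted, preds$truth)
  }
  n <- nrow(preds)
  curve <- tibble::tibble(threshold = sort(unique(preds$score))) %>%
    dplyr::mutate(
      retained = purrr::map_int(.data$threshold,
                                ~ sum(preds$score >= .x)),
      accuracy = purrr::map_dbl(.data$threshold,
                                ~ mean(correct[preds$score >= .x])),
      retained_fraction = .data$retained / n
    )
  ok <- curve$accuracy >= target
  if (any(ok)) {
    pick <- curve[which(ok)[1], ]  # minimum threshold => largest retained set
    res <- list(threshold = pick$threshold,
                achieved_accuracy = pick$accuracy,
                retained_fraction = pick$retained_fraction,
                attainable = TRUE)
  } else {
    res <- list(threshold = Inf, achieved_accuracy = NA_real_,
                retained_fraction = 0, attainable = FALSE)
  }
  structure(c(res, list(target = target, curve = curve, n = n)),
            class = "denovo_calibration")
}

#' @export
print.denovo_calibration <- function(x, ...) {
  cat(sprintf("<denovo_calibration> target accuracy %.2f on %d predictions\n",
              x$target, x$n))
  if (x$attainable) {
    cat(sprintf("  threshold %.4g: accuracy %.3f, retained %.1f%%\n",
                x$threshold, x$achieved_accuracy,
                100 * x$retained_fraction))
  } else {
    cat("  target not attainable at any score cutoff\n")
  }
  invisible(x)
}

#' @export
tidy.denovo_calibration <- function(x, ...) x$curve

#' @export
glance.denovo_calibration <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 achieved_accuracy = x$achieved_accuracy,
                 retained_fraction = x$retained_fraction,
                 attainable = x$attainable, target = x$target, n = x$n)
}
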