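#' Operating characteristics of a single cutoff
#'
#' Tabulates the 2x2 table of a thresholded score against a binary truth and
#' returns sensitivity, specificity, predictive values and the raw counts.
#'
#' @param scores numeric vector.
#' @param truth logical (or 0/1) vector, same length; both classes must be
#'   present.
#' @param cutoff the decision threshold.
#' @param direction `"ge"`: positive if score >= cutoff (default);
#'   `"gt"`: positive if score > cutoff; `"le"`/`"lt"` for scores that fall
#'   with disease.
#' @return list of class `op_chars`: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, and `counts` (tp, fp, tn, fn).
#' @export
operating_characteristics <- function(scores, truth, cutoff,
                                      direction = c("ge", "gt", "le", "lt")) {
  direction <- match.arg(direction)
  if (length(scores) != length(truth)) stopf("scores and truth differ in length")
  if (anyNA(scores) || anyNA(truth)) stopf("scores and truth must be complete")
  truth <- as.logical(truth)
  if (!any(truth)) stopf("no positive subjects in truth")
  if (all(truth)) stopf("no negative subjects in truth")
  pos <- switch(direction,
                ge = scores >= cutoff, gt = scores > cutoff,
                le = scores <= cutoff, lt = scores < cutoff)
  tp <- sum(pos & truth); fp <- sum(pos & !truth)
  fn <- sum(!pos & truth); tn <- sum(!pos & !truth)
  structure(list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
    npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn)
  ), class = "op_chars")
}

#' @export
print.op_chars <- function(x, ...) {
  cat(sprintf("<op_chars> Se %.3f  Sp %.3f  PPV %.3f  NPV %.3f  (tp %d fp %d tn %d fn %d)\n",
              x$sensitivity, x$specificity, x$ppv, x$npv,
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"]))
  invisible(x)
}

#' Apply the study's inclusion filters to a cohort
#'
#' Excludes, in a fixed documented order, records with (1) biopsy length below
#' a minimum, (2) missing or out-of-range liver stiffness when VCTE is
#' required, and (3) incomplete score panels. Each record is counted under the
#' first rule it violates.
#'
#' @param cohort a cohort data frame (e.g. from [simulate_cohort()]).
#' @param rules list: `min_biopsy_mm` (default 10), `vcte_required` (default
#'   TRUE), `scores_complete` (character vector of score columns that must be
#'   non-missing; default the seven panel columns present in the cohort).
#' @return the filtered cohort, with attribute `exclusion_log`: a tibble of
#'   (reason, n_excluded) in application order.
#' @export
apply_inclusion_filters <- function(cohort,
                                    rules = list(min_biopsy_mm = 10,
                                                 vcte_required = TRUE,
                                                 scores_complete = NULL)) {
  rules <- modifyList(list(min_biopsy_mm = 10, vcte_required = TRUE,
                           scores_complete = NULL), rules %||% list())
  score_cols <- rules$scores_complete %||%
    intersect(c("fib4", "nfs", "fmv3g", "cmv3g", "vcte_kpa", "agile3p", "agile4"),
              names(cohort))
  keep <- rep(TRUE, nrow(cohort))
  log <- list()

  if (!is.null(rules$min_biopsy_mm) && "biopsy_length_mm" %in% names(cohort)) {
    bad <- keep & (is.na(cohort$biopsy_length_mm) |
                     cohort$biopsy_length_mm < rules$min_biopsy_mm)
    log[["biopsy_length"]] <- sum(bad)
    keep <- keep & !bad
  }
  if (isTRUE(rules$vcte_required) && "vcte_kpa" %in% names(cohort)) {
    bad <- keep & (is.na(cohort$vcte_kpa) | cohort$vcte_kpa < 1.5 |
                     cohort$vcte_kpa > 75)
    log[["vcte_failure"]] <- sum(bad)
    keep <- keep & !bad
  }
  if (length(score_cols)) {
    inc <- rowSums(is.na(as.data.frame(cohort)[, score_cols, drop = FALSE])) > 0
    bad <- keep & inc
    log[["missing_scores"]] <- sum(bad)
    keep <- keep & !bad
  }

  out <- cohort[keep, , drop = FALSE]
  attr(out, "exclusion_log") <- tibble::tibble(
    reason = names(log), n_excluded = as.integer(unlist(log, use.names = FALSE))
  )
  out
}
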