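# DeLong placements via midranks (Sun & Xu 2014): O(n log n), tie-safe.
# V10_i = (R_i - R+_i)/n_neg for positives, V01_j = 1 - (R_j - R-_j)/n_pos.
delong_placements <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

check_binary_truth <- function(truth) {
  truth <- as.logical(truth)
  if (anyNA(truth)) stopf("truth contains missing values")
  if (!any(truth)) stopf("no positive subjects in truth")
  if (all(truth)) stopf("no negative subjects in truth")
  truth
}

#' AUROC with DeLong confidence interval
#'
#' Mann-Whitney (midrank) estimator of the area under the ROC curve — ties
#' count one half — with the DeLong placement-based variance and a 95% normal
#' confidence interval truncated to `[0, 1]`.
#'
#' @param scores numeric vector (larger = more diseased).
#' @param truth logical (or 0/1) vector; both classes required.
#' @return object of class `auroc_result`: `auroc`, `ci95`, `se`, `n_pos`,
#'   `n_neg`.
#' @examples
#' auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auroc   # 1
#' @export
auroc <- function(scores, truth) {
  truth <- check_binary_truth(truth)
  if (length(scores) != length(truth)) stopf("scores and truth differ in length")
  if (anyNA(scores)) stopf("scores contain missing values")
  pl <- delong_placements(scores, truth)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(v)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  structure(list(auroc = pl$auc, ci95 = ci, se = se,
                 n_pos = pl$m, n_neg = pl$n),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auroc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two paired AUROCs
#'
#' Two-sided comparison of the AUROCs of two scores measured on the same
#' subjects, using the DeLong paired placement covariance.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param truth logical (or 0/1) vector; both classes required.
#' @return list: `auroc_a`, `auroc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  truth <- check_binary_truth(truth)
  if (length(scores_a) != length(truth) || length(scores_b) != length(truth)) {
    stopf("scores_a, scores_b and truth must be paired (same length)")
  }
  if (anyNA(scores_a) || anyNA(scores_b)) stopf("scores contain missing values")
  pa <- delong_placements(scores_a, truth)
  pb <- delong_placements(scores_b, truth)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (v <= .Machine$double.eps) {
    z <- 0
  } else {
    z <- (pa$auc - pb$auc) / sqrt(v)
  }
  list(auroc_a = pa$auc, auroc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Binned calibration of predicted risks
#'
#' Groups predictions into fixed-width risk bins and contrasts the mean
#' predicted risk with the observed event prevalence per bin. Empty bins are
#' kept in the table (count 0, prevalence NA), never silently dropped. The
#' mean signed difference (predicted minus observed, averaged over non-empty
#' bins) summarises the calibration; a count-weighted version is also
#' returned.
#'
#' @param predicted predicted probabilities in `[0, 1]`.
#' @param truth logical (or 0/1) outcomes.
#' @param breaks bin boundaries (default width-0.1 bins); bins are
#'   `[b_k, b_{k+1})`, last bin closed.
#' @return object of class `calibration_table`: `table` (tibble with bin,
#'   n, mean_predicted, observed_prevalence), `mean_signed_diff`,
#'   `mean_signed_diff_weighted`, `n_empty_bins`.
#' @export
calibration_analysis <- function(predicted, truth, breaks = seq(0, 1, 0.1)) {
  truth <- as.logical(truth)
  if (length(predicted) != length(truth)) stopf("predicted and truth differ in length")
  if (anyNA(predicted) || anyNA(truth)) stopf("inputs must be complete")
  if (any(predicted < 0) || any(predicted > 1)) stopf("predicted must lie in [0, 1]")
  k <- length(breaks) - 1L
  idx <- pmin(findInterval(predicted, breaks, rightmost.closed = TRUE), k)
  tab <- tibble::tibble(
    bin = seq_len(k),
    low = breaks[-length(breaks)],
    high = breaks[-1],
    n = vapply(seq_len(k), function(b) sum(idx == b), integer(1))
  )
  tab$mean_predicted <- vapply(seq_len(k), function(b) {
    if (tab$n[b] == 0L) NA_real_ else mean(predicted[idx == b])
  }, numeric(1))
  tab$observed_prevalence <- vapply(seq_len(k), function(b) {
    if (tab$n[b] == 0L) NA_real_ else mean(truth[idx == b])
  }, numeric(1))
  nz <- tab$n > 0L
  d <- tab$mean_predicted[nz] - tab$observed_prevalence[nz]
  structure(list(
    table = tab,
    mean_signed_diff = mean(d),
    mean_signed_diff_weighted = sum(d * tab$n[nz]) / sum(tab$n[nz]),
    n_empty_bins = sum(!nz)
  ), class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("mean signed difference (pred - obs): %+.3f (weighted %+.3f); %d empty bin(s)\n",
              x$mean_signed_diff, x$mean_signed_diff_weighted, x$n_empty_bins))
  invisible(x)
}

#' Diagnostic accuracy report of the study algorithm
#'
#' Scores final diagnoses against biopsy stages. A diagnosis is correct when
#' F0-2 matches stage <= 2, F34 matches stage 3 or 4 (stage 4 counts as
#' correct for the advanced-fibrosis claim; the F4-specific confusion is
#' reported separately), and F4 matches stage 4. Biopsy-category patients
#' are excluded from the accuracy numerator and reported as the biopsy rate;
#' an inclusive accuracy counting them as incorrect is also emitted.
#' Off-by-one misclassification is defined on the ordered grouping
#' {F0-2, F3, F4}.
#'
#' @param diagnosis vector of final diagnoses (`"F0-2"`, `"Biopsy"`, `"F34"`,
#'   `"F4"`).
#' @param stages integer biopsy stages 0..4 (required).
#' @return object of class `accuracy_report`: `n`, `category_counts`,
#'   `biopsy_rate`, `accuracy_excluding_biopsy` (NaN when every diagnosis is
#'   Biopsy), `accuracy_including_biopsy`, `off_by_one_fraction` (among
#'   misclassified non-biopsy patients), `f4_among_f34_category`, and the
#'   `confusion` tibble.
#' @export
accuracy_report <- function(diagnosis, stages) {
  if (anyNA(stages)) stopf("stages missing for some subjects")
  if (!all(stages %in% 0:4)) stopf("stages must lie in 0..4")
  d <- as.character(diagnosis)
  if (length(d) != length(stages)) stopf("diagnosis and stages differ in length")
  bad <- setdiff(unique(d), .diagnosis_levels)
  if (length(bad)) stopf("unknown diagnosis value(s): %s", paste(bad, collapse = ", "))

  n <- length(d)
  is_biopsy <- d == "Biopsy"
  correct <- (d == "F0-2" & stages <= 2) |
    (d == "F34" & stages >= 3) |
    (d == "F4" & stages == 4)

  # ordered severity grouping for the off-by-one accounting
  stage_grp <- ifelse(stages <= 2, 1L, ifelse(stages == 3, 2L, 3L))
  diag_grp <- ifelse(d == "F0-2", 1L, ifelse(d == "F34", 2L, 3L))
  mis <- !is_biopsy & !correct
  off_by_one <- if (any(mis)) {
    mean(abs(diag_grp[mis] - stage_grp[mis]) == 1L)
  } else NaN

  assessed <- n - sum(is_biopsy)
  confusion <- tibble::as_tibble(as.data.frame(table(
    diagnosis = factor(d, levels = .diagnosis_levels),
    stage = factor(stages, levels = 0:4)
  )))

  structure(list(
    n = n,
    category_counts = table(factor(d, levels = .diagnosis_levels)),
    biopsy_rate = sum(is_biopsy) / n,
    accuracy_excluding_biopsy = if (assessed > 0) sum(correct) / assessed else NaN,
    accuracy_including_biopsy = sum(correct) / n,
    off_by_one_fraction = off_by_one,
    f4_among_f34_category = if (any(d == "F34")) {
      mean(stages[d == "F34"] == 4)
    } else NaN,
    confusion = confusion
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report: n = %d>\n", x$n))
  print(x$category_counts)
  cat(sprintf("accuracy %.1f%% (excl. biopsy) / %.1f%% (incl.), biopsy rate %.1f%%, off-by-one %.1f%%\n",
              100 * x$accuracy_excluding_biopsy,
              100 * x$accuracy_including_biopsy,
              100 * x$biopsy_rate,
              100 * x$off_by_one_fraction))
  invisible(x)
}

#' Descriptive two-group comparison
#'
#' Continuous variables are compared with the two-sided Mann-Whitney test;
#' categorical variables with the chi-squared test, switching to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param a,b the two groups: numeric vectors (continuous) or factors /
#'   character vectors (categorical).
#' @param type `"continuous"` or `"categorical"`; guessed from the input
#'   class when omitted.
#' @return list: `method`, `statistic`, `p`.
#' @export
descriptive_compare <- function(a, b, type = NULL) {
  if (length(a) == 0L || length(b) == 0L) stopf("both groups must be non-empty")
  if (is.null(type)) {
    type <- if (is.numeric(a) && is.numeric(b)) "continuous" else "categorical"
  }
  type <- match.arg(type, c("continuous", "categorical"))
  if (type == "continuous") {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    list(method = "mann-whitney", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    lev <- union(unique(as.character(a)), unique(as.character(b)))
    tab <- rbind(table(factor(as.character(a), levels = lev)),
                 table(factor(as.character(b), levels = lev)))
    exp_counts <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
    if (any(exp_counts < 5)) {
      ht <- fisher.test(tab)
      list(method = "fisher", statistic = NA_real_, p = ht$p.value)
    } else {
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      list(method = "chi-squared", statistic = unname(ht$statistic), p = ht$p.value)
    }
  }
}

#' Spearman rank correlation
#'
#' Average-rank (midrank) Spearman coefficient, as used to relate biopsy
#' morphometry areas to fibrosis stage.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return the correlation Rs.
#' @export
spearman_rs <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stopf("inputs must be complete")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("Spearman correlation undefined for a constant vector")
  }
  cor(x, y, method = "spearman")
}
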