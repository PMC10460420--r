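test_that("AUROC handles separable, tied and mixed data against the pair oracle", {
  expect_equal(auroc(c(1, 2, 8, 9), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(auroc(rep(3, 10), rep(c(0, 1), 5))$auroc, 0.5)
  scores <- c(1, 3, 3, 5, 2, 3, 7, 8)
  truth <- c(0, 0, 1, 0, 1, 1, 1, 1)
  expect_equal(auroc(scores, truth)$auroc, pair_auroc(scores, truth))
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "negative")
})

test_that("AUROC equals the exhaustive pair mean on random tied instances", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    scores <- sample(1:6, n, replace = TRUE)  # heavy ties
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    expect_equal(auroc(scores, truth)$auroc, pair_auroc(scores, truth))
  }
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(92)
  scores <- rnorm(300)
  truth <- runif(300) < 0.4
  a <- auroc(scores, truth)
  b <- auroc(exp(scores), truth)
  expect_equal(a$auroc, b$auroc)
  expect_equal(a$se, b$se)
  expect_true(a$ci95[1] <= a$auroc && a$auroc <= a$ci95[2])
})

test_that("DeLong variance and CI agree with the pROC reference", {
  set.seed(93)
  n <- 400
  stage <- runif(n) < 0.3
  s1 <- rnorm(n, mean = stage * 1.2)
  a <- auroc(s1, stage)
  ref <- pROC::ci.auc(pROC::roc(stage, s1, quiet = TRUE), method = "delong")
  expect_equal(a$auroc, as.numeric(ref[2]))
  expect_equal(a$ci95, as.numeric(ref[c(1, 3)]), tolerance = 1e-8)
})

test_that("DeLong test of a score against itself is exactly null", {
  set.seed(94)
  s <- rnorm(100); y <- runif(100) < 0.5
  res <- delong_test(s, s, y)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  # antisymmetry in the pair order
  s2 <- s + rnorm(100, sd = 0.5)
  ab <- delong_test(s, s2, y)
  ba <- delong_test(s2, s, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_error(delong_test(s, s2[-1], y), "paired")
})

test_that("DeLong paired p agrees with pROC and a permutation oracle", {
  set.seed(95)
  n <- 120
  y <- runif(n) < 0.4
  a <- rnorm(n, mean = y * 1.0)
  b <- 0.6 * a + rnorm(n, mean = y * 0.4, sd = 0.8)
  res <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)

  # permutation oracle: per-subject swap of the two paired scores under H0
  obs <- abs(res$auroc_a - res$auroc_b)
  B <- 2000
  perm <- replicate(B, {
    swap <- runif(n) < 0.5
    aa <- ifelse(swap, b, a)
    bb <- ifelse(swap, a, b)
    abs(pair_auroc(aa, y) - pair_auroc(bb, y))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  # MC SE of the permutation estimate plus asymptotic-vs-exact slack
  tol <- 3 * sqrt(p_perm * (1 - p_perm) / B) + 0.03
  expect_lt(abs(res$p - p_perm), tol)
})

test_that("DeLong test holds its size under the null", {
  set.seed(96)
  n <- 150
  rej <- replicate(1000, {
    y <- c(rep(TRUE, 45), rep(FALSE, n - 45))
    common <- rnorm(n, mean = y * 1.0)
    a <- common + rnorm(n, sd = 0.8)
    b <- common + rnorm(n, sd = 0.8)   # equally informative by symmetry
    delong_test(a, b, y)$p < 0.05
  })
  # 3 Monte-Carlo standard errors of the rejection rate at 1000 replicates
  expect_lt(abs(mean(rej) - 0.05), 0.021)
})

test_that("calibration table matches a group-by oracle and keeps empty bins", {
  set.seed(97)
  pred <- runif(400, 0, 0.55)   # upper bins empty
  y <- runif(400) < pred
  ct <- calibration_analysis(pred, y)
  expect_equal(sum(ct$table$n), 400)
  expect_gt(ct$n_empty_bins, 0)
  idx <- pmin(findInterval(pred, seq(0, 1, 0.1), rightmost.closed = TRUE), 10)
  for (b in unique(idx)) {
    expect_equal(ct$table$mean_predicted[b], mean(pred[idx == b]))
    expect_equal(ct$table$observed_prevalence[b], mean(y[idx == b]))
  }
})

test_that("calibration summary detects forced miscalibration and perfection", {
  set.seed(98)
  n <- 40000
  y <- runif(n) < 0.1
  ct <- calibration_analysis(rep(0.5, n), y)
  expect_equal(ct$mean_signed_diff, 0.4, tolerance = 0.02)
  p_true <- runif(n)
  y2 <- runif(n) < p_true
  ct2 <- calibration_analysis(p_true, y2)
  expect_equal(ct2$mean_signed_diff, 0, tolerance = 0.02)
})

test_that("accuracy report covers degenerate, oracle and hand-tabulated cases", {
  expect_error(accuracy_report(c("F4", "F0-2"), c(NA, 2)), "missing")

  all_biopsy <- accuracy_report(rep("Biopsy", 5), c(0, 1, 2, 3, 4))
  expect_true(is.nan(all_biopsy$accuracy_excluding_biopsy))
  expect_equal(all_biopsy$biopsy_rate, 1)

  oracle <- accuracy_report(c("F0-2", "F0-2", "F0-2", "F34", "F4"), 0:4)
  expect_equal(oracle$accuracy_excluding_biopsy, 1)
  expect_equal(oracle$biopsy_rate, 0)

  # hand-tabulated toy confusion: 10 patients
  d <- c("F0-2", "F0-2", "F34", "F34", "F4", "F4", "Biopsy", "Biopsy", "F0-2", "F34")
  s <- c(1, 3, 4, 2, 4, 3, 0, 4, 2, 3)
  rep_ <- accuracy_report(d, s)
  # correct: 1 (F0-2/1), 3 (F34/4 counts), 5 (F4/4), 9 (F0-2/2), 10 (F34/3) = 5 of 8 assessed
  expect_equal(rep_$accuracy_excluding_biopsy, 5 / 8)
  expect_equal(rep_$accuracy_including_biopsy, 5 / 10)
  expect_equal(rep_$biopsy_rate, 0.2)
  # misclassified: 2 (F0-2 vs F3: |1-2|=1), 4 (F34 vs F2: |2-1|=1), 6 (F4 vs F3: |3-2|=1)
  expect_equal(rep_$off_by_one_fraction, 1)
  expect_equal(rep_$f4_among_f34_category, 1 / 3)
  # totals conserved: correct + incorrect + biopsy = n
  expect_equal(sum(rep_$category_counts), rep_$n)
})

test_that("descriptive comparisons pick the documented test paths", {
  set.seed(99)
  x <- rnorm(40)
  same <- descriptive_compare(x, x)
  expect_equal(same$method, "mann-whitney")
  expect_gt(same$p, 0.9)
  # U statistic equals the exhaustive pair count for small samples
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.5, 2.2, 1.1)
  res <- descriptive_compare(a, b)
  U <- sum(outer(a, b, function(u, v) (u > v) + 0.5 * (u == v)))
  expect_equal(res$statistic, U)
  # zero-margin 2x2 drives the Fisher path
  g1 <- c(rep("yes", 3), rep("no", 1))
  g2 <- rep("no", 4)
  expect_equal(descriptive_compare(g1, g2)$method, "fisher")
  big1 <- rep(c("yes", "no"), c(150, 150))
  big2 <- rep(c("yes", "no"), c(90, 210))
  expect_equal(descriptive_compare(big1, big2)$method, "chi-squared")
  expect_error(descriptive_compare(numeric(0), 1:3), "non-empty")
})

test_that("Spearman correlation handles ties via midranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rs(x, x), 1)
  expect_equal(spearman_rs(x, -x), -1)
  set.seed(100)
  xt <- sample(1:4, 30, replace = TRUE)
  yt <- xt + sample(0:2, 30, replace = TRUE)
  manual <- cor(rank(xt), rank(yt))  # midrank Pearson
  expect_equal(spearman_rs(xt, yt), manual)
  expect_error(spearman_rs(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rs(1:2, 1:2), "at least 3")
})
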