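test_that("Agile3+/4 groups honour the published boundary conventions", {
  expect_equal(agile_classify(0.30, 0.05), 1L)
  expect_equal(agile_classify(0.50, 0.10), 2L)
  expect_equal(agile_classify(0.70, 0.50), 4L)
  expect_equal(agile_classify(0.679, 0.474), 3L)  # Agile4 <= 0.474 inclusive
  expect_equal(agile_classify(0.678, 0.99), 2L)   # below the 0.679 rule-in
  expect_equal(agile_classify(0.451, 0.01), 2L)   # low boundary belongs to grp 2
  expect_error(agile_classify(1.2, 0.1), "\\[0, 1\\]")
  expect_error(agile_classify(0.9, NA), "agile4 required")
  expect_equal(agile_classify(0.3, NA), 1L)       # Agile4 not consulted
})

test_that("FM/CM groups honour the published boundary conventions", {
  expect_equal(fmcm_classify(0.20, 0.02), 1L)
  expect_equal(fmcm_classify(0.91, 0.40), 3L)     # CMV3G <= 0.40 inclusive
  expect_equal(fmcm_classify(0.80, 0.41), 4L)
  expect_equal(fmcm_classify(0.76, 0.99), 2L)     # group 3 needs FMV3G > 0.76
  expect_equal(fmcm_classify(0.31, 0.01), 2L)
  expect_error(fmcm_classify(0.9, NA), "cmv3g required")
})

test_that("group assignment is scale-exact near boundaries", {
  eps <- 1e-10
  expect_equal(agile_classify(0.451 - eps, 0.1), 1L)
  expect_equal(agile_classify(0.451 + eps, 0.1), 2L)
  expect_equal(agile_classify(0.679, 0.474 + eps), 4L)
  expect_equal(fmcm_classify(0.76 + eps, 0.40 + eps), 4L)
})

test_that("combination map validation catches malformed maps", {
  m <- default_combination_map()
  expect_silent(fibrostage:::check_combination_map(m))
  expect_error(fibrostage:::check_combination_map(m[-1, ]), "misses cell")
  expect_error(fibrostage:::check_combination_map(rbind(m, m[1, ])), "duplicated")
  m2 <- m; m2$diagnosis[1] <- "F9"
  expect_error(fibrostage:::check_combination_map(m2), "diagnoses")
})

test_that("study algorithm short-circuits group 1 before blood testing", {
  co <- tibble::tibble(agile3p = 0.30, agile4 = NA_real_,
                       fmv3g = NA_real_, cmv3g = NA_real_)
  res <- study_algorithm(co)
  expect_equal(as.character(res$final_diagnosis), "F0-2")
  expect_equal(res$tests_used, "Agile3+/Agile4")
  expect_true(is.na(res$fmcm_group))
})

test_that("blood tests are demanded exactly when the Agile group is 2+", {
  co <- tibble::tibble(agile3p = 0.60, agile4 = 0.1,
                       fmv3g = NA_real_, cmv3g = NA_real_)
  expect_error(study_algorithm(co), "fmv3g/cmv3g required")
})

test_that("double rule-in agreement yields F4; cohort counts match the map", {
  co <- tibble::tibble(agile3p = 0.80, agile4 = 0.60, fmv3g = 0.90, cmv3g = 0.55)
  expect_equal(as.character(study_algorithm(co)$final_diagnosis), "F4")

  big <- default_cohort(5000, seed = 21)
  res <- study_algorithm(big)
  # exhaustive cell-by-cell lookup oracle
  map <- default_combination_map()
  ag <- agile_classify(big$agile3p, big$agile4)
  fg <- fmcm_classify(big$fmv3g, big$cmv3g)
  oracle <- character(nrow(big))
  for (i in seq_len(nrow(big))) {
    oracle[i] <- if (ag[i] == 1L) "F0-2" else
      map$diagnosis[map$agile_group == ag[i] & map$fmcm_group == fg[i]]
  }
  expect_identical(as.character(res$final_diagnosis), oracle)
  expect_identical(table(res$final_diagnosis), table(factor(oracle,
    levels = c("F0-2", "Biopsy", "F34", "F4"))))
})

test_that("classification result invariants hold on a simulated cohort", {
  big <- default_cohort(5000, seed = 21)
  res <- study_algorithm(big)
  # group 1 => no blood group, F0-2; final F4 only from agile group 4
  expect_true(all(is.na(res$fmcm_group[res$agile_group == 1L])))
  expect_true(all(res$final_diagnosis[res$agile_group == 1L] == "F0-2"))
  expect_true(all(res$agile_group[res$final_diagnosis == "F4"] == 4L))
})

test_that("EASL comparator triages through its three tiers", {
  co <- toy_panel_cohort()
  res <- easl_pathway(co)
  # decision-tree oracle, hand-applied with the default thresholds
  expect_equal(res$tier_used, c(1L, 3L, 3L, 3L, 1L, 1L))
  expect_equal(as.character(res$easl_diagnosis),
               c("F0-2", "Biopsy", "F34", "F34", "F0-2", "F0-2"))
  # all tiers concordant high
  hi <- tibble::tibble(fib4 = 4, vcte_kpa = 20, fmv3g = 0.9)
  expect_equal(as.character(easl_pathway(hi)$easl_diagnosis), "F34")
  expect_error(easl_pathway(tibble::tibble(fib4 = 1)), "needs column")
})

test_that("cirrhosis zones map diagnoses deterministically", {
  z <- cirrhosis_zones(c("F0-2", "Biopsy", "F34", "F4"))
  expect_equal(as.character(z),
               c("rule-out", "rule-out", "undetermined", "rule-in"))
  expect_error(cirrhosis_zones("F7"), "unknown diagnosis")
})
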