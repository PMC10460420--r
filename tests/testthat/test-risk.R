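test_that("null-signal fit gives flat slopes and prevalence intercept", {
  set.seed(81)
  n <- 20000
  co <- tibble::tibble(
    stage = sample(0:4, n, replace = TRUE, prob = c(.12, .23, .27, .26, .12)),
    agile3p = runif(n), agile4 = runif(n), fmv3g = runif(n), cmv3g = runif(n)
  )
  m <- fit_risk_model(co, "F4")
  se <- sqrt(diag(m$vcov))
  expect_true(all(abs(m$coefficients[-1]) < 3 * se[-1]))
  expect_equal(unname(m$coefficients[1]), qlogis(mean(co$stage == 4)),
               tolerance = 0.15)
})

test_that("the score equations vanish at the fitted optimum", {
  co <- default_cohort(5000, seed = 21)
  m <- fit_risk_model(co, "F34")
  X <- cbind(1, fibrostage:::risk_design(co$agile3p, co$agile4,
                                         co$fmv3g, co$cmv3g))
  mu <- predict_risk(m, co)
  grad <- crossprod(X, (co$stage >= 3) - mu)
  expect_lt(max(abs(grad)) / nrow(co), 1e-7)
})

test_that("too few events or incomplete panels are refused", {
  co <- default_cohort(5000, seed = 21)
  expect_error(fit_risk_model(co[1:100, ], "F4"), "events")
  co2 <- co; co2$cmv3g[5] <- NA
  expect_error(fit_risk_model(co2, "F4"), "complete")
})

test_that("predicted risk is monotone in each score under positive slopes", {
  co <- default_cohort(5000, seed = 21)
  m <- fit_risk_model(co, "F4")
  expect_true(all(m$coefficients[-1] > 0))
  base <- predict_risk(m, 0.80, 0.50, 0.85, 0.30)
  expect_gt(predict_risk(m, 0.85, 0.50, 0.85, 0.30), base)
  expect_gt(predict_risk(m, 0.80, 0.60, 0.85, 0.30), base)
  expect_gt(predict_risk(m, 0.80, 0.50, 0.90, 0.30), base)
  # hinge: Agile4 only acts beyond the Agile3+ switch point
  expect_equal(predict_risk(m, 0.50, 0.10, 0.50, 0.20),
               predict_risk(m, 0.50, 0.90, 0.50, 0.20))
})

test_that("all-zero coefficients predict risk one half", {
  m <- structure(list(target = "F4",
                      coefficients = c(0, 0, 0, 0, 0),
                      cutpoints = default_band_cutpoints("F4"),
                      switch_points = c(elasto = 0.678, blood = 0.76)),
                 class = "fib_risk_model")
  expect_equal(predict_risk(m, 0.3, 0.2, 0.5, 0.1), 0.5)
  grid <- build_chart(m, resolution = 21)
  expect_true(all(grid$risk == 0.5))
  expect_equal(length(unique(grid$band)), 1L)
})

test_that("band assignment is a half-open partition matching a linear scan", {
  cuts <- default_band_cutpoints("F4")
  expect_equal(assign_band(cuts, 0.01), 1L)
  expect_equal(assign_band(cuts, 0.05), 2L)   # boundary goes to the upper band
  expect_equal(assign_band(cuts, 0.999), 7L)
  expect_error(assign_band(cuts, 1.2), "\\[0, 1\\]")
  set.seed(82)
  risks <- runif(500)
  scan <- vapply(risks, function(r) {
    b <- 1L
    for (cpt in cuts) if (r >= cpt) b <- b + 1L
    b
  }, integer(1))
  expect_identical(assign_band(cuts, risks), scan)
  # every risk maps to exactly one band
  expect_true(all(assign_band(cuts, risks) %in% 1:7))
})

test_that("chart grid equals pointwise prediction and respects its bands", {
  co <- default_cohort(5000, seed = 21)
  m <- fit_risk_model(co, "F34")
  grid <- build_chart(m, resolution = 41)
  expect_equal(nrow(grid), 41 * 41)
  i <- seq(1, nrow(grid), by = 37)
  expect_equal(grid$risk[i],
               predict_risk(m, grid$agile3p[i], grid$agile4[i],
                            grid$fmv3g[i], grid$cmv3g[i]))
  expect_identical(grid$band, assign_band(m, grid$risk))
  cuts <- c(0, m$cutpoints, 1)
  expect_true(all(grid$risk >= cuts[grid$band] - 1e-12))
  expect_true(all(grid$risk <= cuts[grid$band + 1L] + 1e-12))
})

test_that("band conformance: observed prevalence falls in the band interval", {
  der <- default_cohort(30000, seed = 5)
  val <- default_cohort(30000, seed = 61)
  m <- fit_risk_model(der, "F34")
  risk <- predict_risk(m, val)
  band <- assign_band(m, risk)
  cuts <- c(0, m$cutpoints, 1)
  y <- val$stage >= 3
  for (b in sort(unique(band))) {
    nb <- sum(band == b)
    if (nb < 200) next
    obs <- mean(y[band == b])
    se <- sqrt(obs * (1 - obs) / nb)
    expect_true(obs >= cuts[b] - 3 * se - 0.01 &&
                  obs <= cuts[b + 1L] + 3 * se + 0.01,
                label = sprintf("band %d prevalence %.3f within [%.2f, %.2f]",
                                b, obs, cuts[b], cuts[b + 1L]))
  }
})
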