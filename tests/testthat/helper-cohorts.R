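# shared fixtures, built in code

# memoised default-config cohorts so several test files can share one draw
.test_cohorts <- new.env(parent = emptyenv())

default_cohort <- function(n, seed) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.test_cohorts[[key]])) {
    .test_cohorts[[key]] <- simulate_cohort(sim_config(n = n, seed = seed))
  }
  .test_cohorts[[key]]
}

# tiny hand-written cohort with known panel values
toy_panel_cohort <- function() {
  tibble::tibble(
    id = 1:6,
    agile3p = c(0.30, 0.50, 0.70, 0.80, 0.679, 0.10),
    agile4  = c(0.05, 0.10, 0.50, 0.30, 0.474, 0.01),
    fmv3g   = c(0.20, 0.25, 0.80, 0.90, 0.50, 0.10),
    cmv3g   = c(0.02, 0.05, 0.50, 0.30, 0.10, 0.01),
    fib4    = c(0.8, 1.5, 3.0, 2.5, 1.2, 0.5),
    vcte_kpa = c(5.0, 9.0, 20.0, 15.0, 7.0, 4.0)
  )
}

# brute-force AUROC over all positive-negative pairs (ties count 1/2)
pair_auroc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
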