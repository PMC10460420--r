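#' Simulate a synthetic biopsy-staged NAFLD cohort
#'
#' Draws `config$n` subjects with a biopsy fibrosis stage, the seven
#' non-invasive test scores on their native scales, biopsy morphometry areas,
#' and (optionally) back-filled raw labs. Each test's latent severity is
#' normal around its calibrated stage mean; the latent noise across tests is
#' drawn through a Gaussian copula; the native score is the test's strictly
#' increasing quantile link applied to the latent grade, so that marginal
#' quartiles and stage-contrast AUROCs reproduce the calibration targets.
#'
#' Reproducibility: all draws use streams derived from `config$seed`
#' ([derive_seed()]); the same config yields a bit-identical cohort.
#'
#' @param config a [sim_config()].
#' @return a tibble of class `fib_cohort`, one row per subject, with columns
#'   `id`, `stage`, the seven scores (`fib4`, `nfs`, `fmv3g`, `cmv3g`,
#'   `vcte_kpa`, `agile3p`, `agile4`), morphometry areas, `biopsy_length_mm`,
#'   and raw labs when back-filled. Attributes: `seed`, `labs_backfilled`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 500, seed = 1))
#' median(co$agile3p)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  n <- config$n
  if (n == 0L) {
    out <- empty_cohort()
    attr(out, "seed") <- config$seed
    return(out)
  }

  stages <- sample_stages(n, config$stage_dist, seed = config$seed)

  # correlated latent noise through the Gaussian copula
  L <- chol(config$copula_corr)
  eps <- with_stream(config$seed, "copula", {
    matrix(rnorm(n * length(.fib_tests)), nrow = n) %*% L
  })
  colnames(eps) <- .fib_tests

  scores <- lapply(.fib_tests, function(t) {
    cal <- config$calibrations[[t]]
    z <- cal$stage_means[stages + 1L] + cal$sigma * eps[, t]
    apply_link(cal, z)
  })
  names(scores) <- .fib_tests

  if (config$agile4_mode == "latent-link") {
    # deterministic convex map of the Agile3+ latent grade onto the Agile4
    # native scale: u^k with k > 1 reproduces the exponentially shaped relation
    cal3 <- config$calibrations[["agile3p"]]
    z3 <- cal3$stage_means[stages + 1L] + cal3$sigma * eps[, "agile3p"]
    u3 <- latent_cdf_fast(z3, cal3$stage_means, cal3$dist)
    scores[["agile4"]] <- apply_link_grade(config$calibrations[["agile4"]]$link,
                                           u3^config$agile_link_shape)
  }

  morph <- simulate_morphometry(stages, config$morphometry, seed = config$seed)

  out <- tibble::tibble(
    id = seq_len(n),
    stage = stages,
    fib4 = scores$fib4,
    nfs = scores$nfs,
    fmv3g = scores$fmv3g,
    cmv3g = scores$cmv3g,
    vcte_kpa = scores$vcte,
    agile3p = scores$agile3p,
    agile4 = scores$agile4,
    area_fibrosis_pct = morph$area_fibrosis_pct,
    area_portal_fibrosis_pct = morph$area_portal_fibrosis_pct
  )

  if (config$backfill_labs) out <- backfill_labs(out, config$seed)

  class(out) <- c("fib_cohort", class(out))
  attr(out, "seed") <- config$seed
  attr(out, "labs_backfilled") <- config$backfill_labs
  out
}

empty_cohort <- function() {
  out <- tibble::tibble(
    id = integer(0), stage = integer(0), fib4 = numeric(0), nfs = numeric(0),
    fmv3g = numeric(0), cmv3g = numeric(0), vcte_kpa = numeric(0),
    agile3p = numeric(0), agile4 = numeric(0),
    area_fibrosis_pct = numeric(0), area_portal_fibrosis_pct = numeric(0)
  )
  class(out) <- c("fib_cohort", class(out))
  out
}

# Raw labs consistent with the simulated FIB4: age, ALT and platelets are
# drawn from reference ranges matched to the study cohort's printed
# medians/quartiles, then AST is solved from the FIB4 identity
# AST = FIB4 * platelets * sqrt(ALT) / age (clamped to a physiological
# range, which almost never binds). The remaining labs (sex, BMI, T2DM,
# albumin, biopsy length) are drawn from the printed marginals. These labs
# are plumbing for interface tests, not calibrated joint data: the cohort
# carries a labs_backfilled flag and NFS recomputed from them will not match
# the simulated NFS score.
backfill_labs <- function(cohort, seed) {
  n <- nrow(cohort)
  with_stream(seed, "labs", {
    age <- pmin(pmax(rnorm(n, 57.6, 11), 18), 90)
    sex <- ifelse(runif(n) < 0.591, "male", "female")
    bmi <- rlnorm(n, log(31.6), 0.18)
    t2dm <- runif(n) < 0.513
    # log-sd from printed quartiles: log(q75/q25) / (2 * 0.6745)
    alt <- rlnorm(n, log(55), log(79 / 36) / 1.349)
    platelets <- pmin(pmax(rnorm(n, 222, 62), 30), 600)
    ast <- pmin(pmax(cohort$fib4 * platelets * sqrt(alt) / age, 5), 500)
    # where the AST clamp binds, move platelets instead so the FIB4
    # identity still holds whenever the physiology allows it
    clamped <- ast != cohort$fib4 * platelets * sqrt(alt) / age
    platelets[clamped] <- pmin(pmax(
      ast[clamped] * age[clamped] / (cohort$fib4[clamped] * sqrt(alt[clamped])),
      30), 600)
    albumin <- pmin(pmax(rnorm(n, 43.4, 3.6), 25), 55)
    biopsy_length <- pmax(round(rlnorm(n, log(25), log(33 / 20) / 1.349)), 5)
    tibble::add_column(cohort,
      age = age, sex = sex, bmi = bmi, t2dm = t2dm, ast = ast, alt = alt,
      platelets = platelets, albumin = albumin,
      biopsy_length_mm = biopsy_length
    )
  })
}
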