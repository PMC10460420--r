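#' Default copula correlation across test noise terms
#'
#' Residual (given-stage) correlation of the latent noise across the seven
#' tests: 0.6 within a modality (elastography-based: VCTE, Agile3+, Agile4;
#' blood-based: FIB4, NFS, FibroMeterV3G, CirrhoMeterV3G) and 0.4 across
#' modalities. The shared biopsy stage induces additional marginal
#' correlation on top of this. Values are assumptions (the source study prints
#' only marginal AUROCs), exposed here so they can be replaced.
#'
#' @return a 7x7 positive-definite correlation matrix with unit diagonal.
#' @export
default_copula <- function() {
  modality <- c(fib4 = "blood", nfs = "blood", fmv3g = "blood", cmv3g = "blood",
                vcte = "elasto", agile3p = "elasto", agile4 = "elasto")
  modality <- modality[.fib_tests]
  R <- outer(modality, modality, function(a, b) ifelse(a == b, 0.6, 0.4))
  diag(R) <- 1
  dimnames(R) <- list(.fib_tests, .fib_tests)
  R
}

check_copula <- function(R) {
  if (!is.matrix(R) || nrow(R) != length(.fib_tests) ||
      ncol(R) != length(.fib_tests)) {
    stopf("copula correlation must be a %dx%d matrix", length(.fib_tests),
          length(.fib_tests))
  }
  if (max(abs(R - t(R))) > 1e-10) stopf("copula correlation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stopf("copula correlation must have unit diagonal")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stopf("copula correlation must be positive semi-definite")
  invisible(R)
}

#' Simulation configuration
#'
#' Bundles everything the cohort generator needs: cohort size, stage
#' distribution, per-test calibrations, copula correlation, the Agile4
#' generation mode, morphometry settings and the root seed. With a fixed
#' config (seed included) the generated cohort is bit-reproducible.
#'
#' @param n cohort size (>= 0).
#' @param seed integer root seed; per-operation streams are derived from it
#'   (see [derive_seed()]).
#' @param stage_dist a [stage_distribution()].
#' @param calibrations named list of `test_calibration` objects; defaults to
#'   [default_calibrations()] for the seven tests.
#' @param copula_corr correlation matrix for the test noise terms;
#'   defaults to [default_copula()].
#' @param agile4_mode `"calibrated"` (default) gives Agile4 its own calibrated
#'   latent, correlated with Agile3+ through the copula; `"latent-link"`
#'   derives Agile4 deterministically from the Agile3+ latent grade through
#'   the convex map `u^agile_link_shape`, reproducing the exponentially
#'   shaped relation between the two scores at the cost of forcing Agile4's
#'   AUROCs to equal Agile3+'s.
#' @param agile_link_shape convexity exponent (> 1) for `"latent-link"` mode.
#' @param morphometry settings from [morphometry_settings()].
#' @param backfill_labs if `TRUE` (default), raw labs (age, sex, BMI, T2DM,
#'   AST, ALT, platelets, albumin) are generated from reference ranges, with
#'   platelets solved from the simulated FIB4 so that recomputing FIB4 from
#'   the labs reproduces the simulated score. The labs are flagged
#'   non-authoritative in the cohort attributes.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n,
                       seed,
                       stage_dist = stage_distribution(),
                       calibrations = default_calibrations(stage_dist),
                       copula_corr = default_copula(),
                       agile4_mode = c("calibrated", "latent-link"),
                       agile_link_shape = 2,
                       morphometry = morphometry_settings(stage_dist),
                       backfill_labs = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stopf("n must be a single non-negative integer")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("seed must be a single integer")
  }
  if (!is_stage_distribution(stage_dist)) stage_dist <- stage_distribution(stage_dist)
  if (!all(.fib_tests %in% names(calibrations))) {
    stopf("calibrations must cover all tests: %s",
          paste(setdiff(.fib_tests, names(calibrations)), collapse = ", "))
  }
  check_copula(copula_corr)
  agile4_mode <- match.arg(agile4_mode)
  if (agile4_mode == "latent-link" &&
      (!is.numeric(agile_link_shape) || agile_link_shape <= 1)) {
    stopf("agile_link_shape must be > 1 (convex) in latent-link mode")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), stage_dist = stage_dist,
         calibrations = calibrations[.fib_tests], copula_corr = copula_corr,
         agile4_mode = agile4_mode, agile_link_shape = agile_link_shape,
         morphometry = morphometry, backfill_labs = isTRUE(backfill_labs)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: n = %d, seed = %d, agile4 mode = %s>\n",
              x$n, x$seed, x$agile4_mode))
  invisible(x)
}
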