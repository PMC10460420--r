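#' Morphometry generator settings
#'
#' Quantitative biopsy morphometry is emulated as a log-normal area whose
#' log-location increases with fibrosis stage: `log(area) = a_s + noise`.
#' The stage locations are fixed, field-realistic area percentages (whole
#' fibrosis: 2, 4, 6, 10, 22%; portal fibrosis: 0.6, 1.2, 2.5, 5, 12%);
#' the noise scale of each trait is solved by [calibrate_morph_noise()] so
#' that the model-implied large-sample Spearman correlation with stage hits
#' a stated target (defaults: 0.548 for whole-area, 0.711 for portal-area).
#'
#' @param stage_dist a [stage_distribution()] (determines stage ties, hence
#'   the attainable Spearman range).
#' @param target_rs_whole,target_rs_portal Spearman targets with stage.
#' @param stage_area_whole,stage_area_portal median area (%) per stage F0..F4,
#'   strictly increasing.
#' @return a list with the stage log-locations and the calibrated noise scales.
#' @export
morphometry_settings <- function(stage_dist = stage_distribution(),
                                 target_rs_whole = 0.548,
                                 target_rs_portal = 0.711,
                                 stage_area_whole = c(2, 4, 6, 10, 22),
                                 stage_area_portal = c(0.6, 1.2, 2.5, 5, 12)) {
  for (a in list(stage_area_whole, stage_area_portal)) {
    if (length(a) != 5L || any(a <= 0) || any(diff(a) <= 0)) {
      stopf("stage areas must be 5 strictly increasing positive percentages")
    }
  }
  list(
    loc_whole = log(stage_area_whole),
    loc_portal = log(stage_area_portal),
    noise_whole = calibrate_morph_noise(target_rs_whole, stage_dist,
                                        log(stage_area_whole)),
    noise_portal = calibrate_morph_noise(target_rs_portal, stage_dist,
                                         log(stage_area_portal)),
    target_rs_whole = target_rs_whole,
    target_rs_portal = target_rs_portal
  )
}

# large-sample Spearman correlation between stage (with ties, midranks) and a
# continuous trait X = loc_s + sigma * eps, eps ~ N(0,1). Monotone transforms
# of X (here exp) leave it unchanged. Derivation: with U_X = F_X(X) uniform and
# U_S the midrank grade of stage, rho = cov(U_X, U_S) / (sd(U_X) sd(U_S)),
# sd(U_X) = 1/sqrt(12), E[U_X | S = s] = sum_t p_t Phi((loc_s - loc_t) /
# (sigma sqrt(2))).
morph_spearman <- function(sigma, dist, loc) {
  p <- unclass(dist)
  u_s <- stage_grades(dist)
  e_ux <- vapply(1:5, function(s) {
    sum(p * pnorm((loc[s] - loc) / (sigma * sqrt(2))))
  }, numeric(1))
  cov_us <- sum(p * (e_ux - 0.5) * (u_s - 0.5))
  sd_us <- sqrt(sum(p * (u_s - 0.5)^2))
  cov_us / (sd_us / sqrt(12))
}

# supremum of morph_spearman as sigma -> 0 (continuous trait perfectly ordered
# by a tied stage): sqrt(12) * sd of the stage midrank grades
max_spearman_with_stage <- function(dist) {
  u_s <- stage_grades(dist)
  p <- unclass(dist)
  sqrt(12 * sum(p * (u_s - 0.5)^2))
}

#' Solve the morphometry noise scale for a Spearman target
#'
#' 1-D root-finding on the analytic large-sample Spearman correlation
#' between stage and the log-normal area trait.
#'
#' @param target_rs Spearman target; must be positive and below the maximal
#'   value attainable given the stage ties (see the noise-free limit).
#' @param dist a [stage_distribution()].
#' @param loc log-scale stage locations (length 5, strictly increasing).
#' @return the noise standard deviation on the log scale.
#' @export
calibrate_morph_noise <- function(target_rs, dist = stage_distribution(),
                                  loc = log(c(2, 4, 6, 10, 22))) {
  if (!is_stage_distribution(dist)) dist <- stage_distribution(dist)
  rs_max <- max_spearman_with_stage(dist)
  if (!is.numeric(target_rs) || length(target_rs) != 1L ||
      target_rs <= 0 || target_rs >= rs_max) {
    stopf("Spearman target must lie in (0, %.4f), the attainable range given stage ties",
          rs_max)
  }
  uniroot(function(s) morph_spearman(s, dist, loc) - target_rs,
          c(1e-6, 100), tol = 1e-12)$root
}

#' Simulate biopsy morphometry areas
#'
#' Draws area-of-fibrosis and area-of-portal-fibrosis percentages for a
#' vector of stages, log-normal around stage-specific locations.
#'
#' @param stages integer vector of stages 0..4.
#' @param settings from [morphometry_settings()]; its calibrated noise scales
#'   are used unless `morph_noise` overrides both.
#' @param seed integer seed.
#' @param morph_noise optional single positive noise scale overriding the
#'   calibrated per-trait scales (useful for studying the noise-free limit).
#' @return a tibble with columns `area_fibrosis_pct`, `area_portal_fibrosis_pct`.
#' @export
simulate_morphometry <- function(stages, settings = morphometry_settings(),
                                 seed, morph_noise = NULL) {
  stopifnot(all(stages %in% 0:4))
  if (!is.null(morph_noise)) {
    if (!is.numeric(morph_noise) || length(morph_noise) != 1L || morph_noise <= 0) {
      stopf("morph_noise must be a single positive value")
    }
    nw <- np <- morph_noise
  } else {
    nw <- settings$noise_whole
    np <- settings$noise_portal
  }
  n <- length(stages)
  with_stream(seed, "morphometry", {
    z <- matrix(rnorm(2 * n), ncol = 2)
    tibble::tibble(
      area_fibrosis_pct =
        pmin(exp(settings$loc_whole[stages + 1L] + nw * z[, 1]), 100),
      area_portal_fibrosis_pct =
        pmin(exp(settings$loc_portal[stages + 1L] + np * z[, 2]), 100)
    )
  })
}
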