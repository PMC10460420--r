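#' Default risk-band cutpoints
#'
#' Seven bands for the cirrhosis (F4) chart, delimited by 5, 10, 20, 40, 60
#' and 80% predicted risk; ten decile bands (10..90%) for the advanced
#' fibrosis (F34) chart. Band intervals are half-open `[low, high)`.
#'
#' @param target `"F4"` or `"F34"`.
#' @return increasing numeric vector of interior cutpoints.
#' @export
default_band_cutpoints <- function(target = c("F4", "F34")) {
  target <- match.arg(target)
  switch(target,
         F4 = c(0.05, 0.10, 0.20, 0.40, 0.60, 0.80),
         F34 = seq(0.1, 0.9, by = 0.1))
}

# hinge design matrix on the composite elastography/blood axes: the
# second-line score of each couple only acts beyond the published switch
# point of its first-line companion
risk_design <- function(agile3p, agile4, fmv3g, cmv3g,
                        switch_points = c(elasto = 0.678, blood = 0.76)) {
  for (v in list(agile3p, agile4, fmv3g, cmv3g)) {
    if (anyNA(v)) stopf("risk model scores must be complete")
  }
  cbind(
    agile3p = agile3p,
    agile4_hinge = agile4 * (agile3p > switch_points[["elasto"]]),
    fmv3g = fmv3g,
    cmv3g_hinge = cmv3g * (fmv3g > switch_points[["blood"]])
  )
}

#' Fit a joint risk model for cirrhosis or advanced fibrosis
#'
#' Maximum-likelihood logistic regression of the histological target on the
#' two score couples with hinge activations at the published switch points:
#' `logit P = b0 + b1*Agile3+ + b2*Agile4*[Agile3+ > 0.678] + b3*FMV3G +
#' b4*CMV3G*[FMV3G > 0.76]`. The hinge form mirrors the charts' composite
#' axes ("move to the second scale beyond the switch point"); it is a
#' declared modelling choice, not a published formula.
#'
#' @param cohort data frame with `stage` (0..4) and the four scores.
#' @param target `"F4"` (stage 4) or `"F34"` (stage 3-4).
#' @param cutpoints band boundaries; default [default_band_cutpoints()].
#' @param min_events minimum number of target-class events (default 50).
#' @return object of class `fib_risk_model`: coefficients, `loglik`,
#'   `converged`, `vcov`, `cutpoints`, `switch_points`, `target`.
#' @export
fit_risk_model <- function(cohort, target = c("F4", "F34"),
                           cutpoints = default_band_cutpoints(target),
                           min_events = 50) {
  target <- match.arg(target)
  need <- c("stage", "agile3p", "agile4", "fmv3g", "cmv3g")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort misses column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(cohort$stage)) stopf("stage missing for some subjects")
  y <- if (target == "F4") cohort$stage == 4L else cohort$stage >= 3L
  if (sum(y) < min_events) {
    stopf("only %d %s events (< %d required)", sum(y), target, min_events)
  }
  if (sum(!y) < min_events) stopf("too few non-events to fit")
  X <- risk_design(cohort$agile3p, cohort$agile4, cohort$fmv3g, cohort$cmv3g)
  dat <- data.frame(y = y, X)
  fit <- glm(y ~ agile3p + agile4_hinge + fmv3g + cmv3g_hinge,
             data = dat, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) stopf("risk model (%s) did not converge", target)
  mu <- fit$fitted.values
  if (min(mu) < 1e-10 || max(mu) > 1 - 1e-10) {
    stopf("risk model (%s): fitted probabilities at the boundary suggest (quasi-)separation; refusing the fit",
          target)
  }
  if (any(diff(cutpoints) <= 0) || any(cutpoints <= 0) || any(cutpoints >= 1)) {
    stopf("cutpoints must be strictly increasing within (0, 1)")
  }
  structure(
    list(target = target, coefficients = coef(fit), vcov = vcov(fit),
         loglik = as.numeric(logLik(fit)), converged = fit$converged,
         n = length(y), n_events = sum(y),
         cutpoints = as.numeric(cutpoints),
         switch_points = c(elasto = 0.678, blood = 0.76)),
    class = "fib_risk_model"
  )
}

#' @export
print.fib_risk_model <- function(x, ...) {
  cat(sprintf("<fib_risk_model: %s, n = %d (%d events), logLik = %.1f>\n",
              x$target, x$n, x$n_events, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict the target risk for score values
#'
#' Inverse-logit of the fitted linear predictor with hinge terms.
#'
#' @param model a [fit_risk_model()] result.
#' @param agile3p,agile4,fmv3g,cmv3g scores in `[0, 1]` (vectorized), or pass
#'   a data frame with those columns as `agile3p`.
#' @return predicted probability of the model's target.
#' @export
predict_risk <- function(model, agile3p, agile4 = NULL, fmv3g = NULL,
                         cmv3g = NULL) {
  if (!inherits(model, "fib_risk_model")) stopf("model must be a fib_risk_model")
  if (is.data.frame(agile3p)) {
    df <- agile3p
    miss <- setdiff(c("agile3p", "agile4", "fmv3g", "cmv3g"), names(df))
    if (length(miss)) stopf("panel misses column(s): %s", paste(miss, collapse = ", "))
    agile3p <- df$agile3p; agile4 <- df$agile4
    fmv3g <- df$fmv3g; cmv3g <- df$cmv3g
  }
  if (is.null(agile4) || is.null(fmv3g) || is.null(cmv3g)) {
    stopf("agile4, fmv3g and cmv3g are all required")
  }
  check_unit(agile3p = agile3p, agile4 = agile4, fmv3g = fmv3g, cmv3g = cmv3g)
  X <- risk_design(agile3p, agile4, fmv3g, cmv3g, model$switch_points)
  eta <- model$coefficients[1] + X %*% model$coefficients[-1]
  as.numeric(plogis(eta))
}

#' Assign a predicted risk to its chart band
#'
#' Bands are the half-open intervals `[0, c1), [c1, c2), ..., [ck, 1]`
#' delimited by the model's cutpoints; a risk equal to a cutpoint falls in
#' the upper band.
#'
#' @param model a `fib_risk_model` (or a numeric cutpoint vector).
#' @param risk probabilities in `[0, 1]`.
#' @return integer band index, 1-based.
#' @export
assign_band <- function(model, risk) {
  cut <- if (inherits(model, "fib_risk_model")) model$cutpoints else model
  if (anyNA(risk) || any(risk < 0) || any(risk > 1)) {
    stopf("risk must lie in [0, 1]")
  }
  findInterval(risk, cut) + 1L
}

#' Build the risk chart grid on the composite axes
#'
#' Each axis is a continuous severity coordinate in `[0, 1]`: below the
#' switch point it is the first-line score itself (Agile3+, FMV3G); beyond it
#' the coordinate moves onto the second-line scale (Agile4, CMV3G), rescaled
#' from the remaining axis range with the first-line score pinned just above
#' its switch point. The grid evaluates [predict_risk()] and [assign_band()]
#' node by node.
#'
#' @param model a `fib_risk_model`.
#' @param resolution nodes per axis (default 201).
#' @return tibble of class `chart_grid`: axis positions, the four implied
#'   scores, `risk` and `band` per node.
#' @export
build_chart <- function(model, resolution = 201) {
  if (!inherits(model, "fib_risk_model")) stopf("model must be a fib_risk_model")
  if (resolution < 2) stopf("resolution must be >= 2")
  sw_e <- model$switch_points[["elasto"]]
  sw_b <- model$switch_points[["blood"]]
  pos <- seq(0, 1, length.out = resolution)

  elasto <- function(u) {
    on2 <- u > sw_e
    list(agile3p = ifelse(on2, sw_e + 1e-3, u),
         agile4 = ifelse(on2, (u - sw_e) / (1 - sw_e), 0))
  }
  blood <- function(u) {
    on2 <- u > sw_b
    list(fmv3g = ifelse(on2, sw_b + 1e-3, u),
         cmv3g = ifelse(on2, (u - sw_b) / (1 - sw_b), 0))
  }

  g <- expand.grid(x_elasto = pos, x_blood = pos)
  e <- elasto(g$x_elasto); b <- blood(g$x_blood)
  risk <- predict_risk(model, e$agile3p, e$agile4, b$fmv3g, b$cmv3g)
  out <- tibble::tibble(
    x_elasto = g$x_elasto, x_blood = g$x_blood,
    agile3p = e$agile3p, agile4 = e$agile4,
    fmv3g = b$fmv3g, cmv3g = b$cmv3g,
    risk = risk, band = assign_band(model, risk)
  )
  class(out) <- c("chart_grid", class(out))
  attr(out, "target") <- model$target
  attr(out, "cutpoints") <- model$cutpoints
  out
}
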