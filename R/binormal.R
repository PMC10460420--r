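#' AUROC of two normal score distributions
#'
#' Closed-form area under the ROC curve when diseased and non-diseased scores
#' are normal with a location shift: `pnorm(delta_mu / sqrt(s0^2 + s1^2))`.
#' This is the analytic kernel the generator calibration inverts.
#'
#' @param delta_mu difference in means (diseased minus non-diseased).
#' @param sigma_pair two positive standard deviations (non-diseased, diseased).
#' @return the AUROC, in (0, 1).
#' @examples
#' binormal_auroc(0, c(1, 1))          # 0.5, no separation
#' binormal_auroc(sqrt(2), c(1, 1))    # pnorm(1)
#' @export
binormal_auroc <- function(delta_mu, sigma_pair = c(1, 1)) {
  stopifnot(is.numeric(delta_mu), length(delta_mu) == 1L, is.finite(delta_mu))
  if (!is.numeric(sigma_pair) || length(sigma_pair) != 2L ||
      any(!is.finite(sigma_pair)) || any(sigma_pair <= 0)) {
    stopf("sigma_pair must be two positive standard deviations")
  }
  pnorm(delta_mu / sqrt(sum(sigma_pair^2)))
}

#' Analytic AUROC of a stage-mixture binormal model
#'
#' For a latent score N(m_s, 1) given stage s with stage prevalences `dist`,
#' the AUROC contrasting positive stages against the rest is the
#' prevalence-weighted average of pairwise binormal terms
#' `pnorm((m_s - m_t)/sqrt(2))` over positive s and negative t.
#'
#' @param means numeric length-5 vector of latent stage means m0..m4.
#' @param dist a [stage_distribution()].
#' @param positive integer stages counted as diseased (e.g. `3:4` for F34,
#'   `4` for F4).
#' @return the mixture AUROC.
#' @export
mixture_auroc <- function(means, dist = stage_distribution(), positive) {
  stopifnot(is.numeric(means), length(means) == 5L, all(is.finite(means)))
  if (!is_stage_distribution(dist)) dist <- stage_distribution(dist)
  positive <- as.integer(positive)
  if (!all(positive %in% 0:4) || length(positive) == 0L ||
      length(positive) == 5L) {
    stopf("positive stages must be a proper non-empty subset of 0..4")
  }
  pos <- positive + 1L
  p <- unclass(dist)
  wp <- p[pos] / sum(p[pos])
  wn <- p[-pos] / sum(p[-pos])
  sum(outer(wp, wn) * pnorm(outer(means[pos], means[-pos], "-") / sqrt(2)))
}
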