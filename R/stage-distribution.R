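#' Fibrosis stage distribution
#'
#' A probability vector over the NASH CRN histological stages F0-F4. The
#' default is the stage composition of a large biopsy-staged NAFLD cohort
#' (printed percentages 12.1, 22.6, 27.1, 26.2, 12.1, renormalized to sum
#' exactly to one; the printed values total 100.1 because of rounding).
#'
#' @param p numeric vector of length 5: probabilities for F0..F4.
#' @return an object of class `stage_distribution` (named numeric vector).
#' @examples
#' d <- stage_distribution()
#' sum(d)            # 1
#' d[["F4"]]         # cirrhosis prevalence
#' @export
stage_distribution <- function(p = c(12.1, 22.6, 27.1, 26.2, 12.1) / 100.1) {
  if (!is.numeric(p) || length(p) != 5L || anyNA(p)) {
    stopf("stage distribution must be 5 finite probabilities (F0..F4)")
  }
  if (any(p < 0) || any(p > 1)) stopf("stage probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12) {
    stopf("stage probabilities must sum to 1 (got %.15f)", sum(p))
  }
  structure(setNames(as.numeric(p), paste0("F", 0:4)),
            class = "stage_distribution")
}

is_stage_distribution <- function(x) inherits(x, "stage_distribution")

#' Sample biopsy fibrosis stages
#'
#' Draws `n` independent stages F0-F4 from a [stage_distribution()].
#'
#' @param n number of subjects (>= 1, or 0 for an empty draw).
#' @param dist a [stage_distribution()].
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @return integer vector of length `n` with values in 0..4.
#' @examples
#' table(sample_stages(1000, stage_distribution(), seed = 1))
#' @export
sample_stages <- function(n, dist = stage_distribution(), seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stopf("n must be a single non-negative integer")
  }
  if (!is_stage_distribution(dist)) dist <- stage_distribution(dist)
  if (n == 0L) return(integer(0))
  with_stream(seed, "stages", {
    sample.int(5L, size = n, replace = TRUE, prob = unclass(dist)) - 1L
  })
}

# midrank grade of each stage under dist: P(S < s) + p_s / 2
stage_grades <- function(dist) {
  p <- unclass(dist)
  cumsum(c(0, p[-5])) + p / 2
}
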