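#' Derive a reproducible sub-stream seed from a root seed
#'
#' Every stochastic operation in the package draws from its own stream derived
#' from one root seed, so that adding or reordering draws in one stage never
#' perturbs another. The derivation rule is fixed and documented: the stream
#' seed is `(root * 2654435761 + index) mod (2^31 - 1)` where `index` is a
#' small integer registered per operation (stages = 1, copula noise = 2,
#' morphometry = 3, lab back-fill = 4, validation split = 5). The multiplier
#' is the Knuth multiplicative-hash constant; the modulus keeps seeds within
#' R's 32-bit integer range.
#'
#' @param root integer root seed.
#' @param index small non-negative integer identifying the operation stream.
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647
  # double-precision modular arithmetic: split the 32-bit constant to avoid
  # exceeding 2^53 in the intermediate product
  r <- ((root %% m) * (2654435761 %% m)) %% m
  as.integer((r + index) %% m)
}

.stream <- list(stages = 1L, copula = 2L, morphometry = 3L, labs = 4L, split = 5L)

with_stream <- function(root, op, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(root, .stream[[op]]))
  expr
}
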