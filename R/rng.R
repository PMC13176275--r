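#' Derive a named RNG substream seed
#'
#' Deterministically maps a master seed plus an arbitrary sequence of string
#' labels (stage, trait, contrast, ...) to a child seed in `[0, 2^31 - 2]`.
#' Substreams keep results order-independent: adding a trait or reordering
#' contrasts never perturbs the draws of another substream.
#'
#' The hash is a 31-bit multiplicative string hash combined with the master
#' seed by a Lehmer step; all arithmetic stays below 2^53 so it is exact in
#' doubles on every platform.
#'
#' @param seed integer master seed.
#' @param ... character labels identifying the substream.
#' @return An integer seed suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "effects", "shoot", "WS vs WW")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (label in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(label)) {
      h <- (h * 31 + code) %% m
    }
    h <- (h * 48271 + 11) %% m # stir between labels
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded computations never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
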