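# Reproducibility helpers: explicit seed scoping and substream derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded sections do not perturb the
#' caller's RNG state. All stochastic operations in the package draw from the
#' session RNG; callers scope them with `with_seed()`.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible substream seed
#'
#' Folds a master seed with integer context labels (e.g. generation number,
#' partition id, gene index) into a 31-bit seed, so per-partition and per-gene
#' random streams are independent of scheduling order.
#'
#' @param master integer master seed.
#' @param ... integer context labels.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629          # prime below 2^31
  s <- as.numeric(master) %% m
  for (k in c(...)) {
    # multiplier small enough that s * mult + k stays exact in doubles
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s)
}
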