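# Hierarchical seed derivation and scoped RNG use.
#
# All stochastic entry points take an integer `seed`; sub-tasks (per topology,
# per stage, per replicate, per generation) derive their own seed by folding
# integer/string labels into a 31-bit multiplicative hash. Derivation is
# counter-based: adding replicates or topologies never perturbs the streams of
# existing ones. All arithmetic stays below 2^53 so it is exact in doubles.

#' Derive a child seed from a root seed and a label path
#'
#' @param seed Integer root seed.
#' @param ... Integer or character labels identifying the sub-stream
#'   (e.g. topology index, stage name, replicate number).
#' @return A positive integer seed strictly below 2^31.
#' @examples
#' deriveSeed(1, "establish", 3L)
#' @export
deriveSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629 # largest prime < 2^31
  h <- as.double(abs(seed)) %% m
  for (p in list(...)) {
    v <- if (is.character(p)) {
      codes <- utf8ToInt(p)
      sum(codes * seq_along(codes))
    } else {
      as.double(p)
    }
    h <- (h * 69069 + (v %% m) + 1) %% m
  }
  as.integer(h + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. A NULL seed evaluates in the ambient state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
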