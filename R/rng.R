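# Counter-based substream seeding: each cell class draws from its own
# L'Ecuyer-CMRG stream derived from the master seed, so e.g. adding CD8
# simulation never perturbs tumor placement.

#' Derive independent RNG substreams from a master seed
#'
#' Returns `n` independent L'Ecuyer-CMRG stream states obtained by repeated
#' application of [parallel::nextRNGStream()] to the state seeded by `seed`.
#' The caller's RNG state and kind are left untouched.
#'
#' @param seed Integer master seed.
#' @param n Number of substreams to derive.
#' @return A list of `n` `.Random.seed`-compatible integer vectors.
#' @keywords internal
rng_substreams <- function(seed, n) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    state <- parallel::nextRNGStream(state)
    streams[[i]] <- state
  }
  streams
}

#' Evaluate an expression under a given RNG stream state
#'
#' Installs `stream` as the RNG state, evaluates `expr`, and restores the
#' previous state afterwards.
#'
#' @param stream A `.Random.seed`-compatible state from [rng_substreams()].
#' @param expr Expression to evaluate.
#' @keywords internal
with_stream <- function(stream, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  assign(".Random.seed", stream, envir = globalenv())
  expr
}
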