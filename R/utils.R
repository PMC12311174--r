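#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All seed-taking functions in the package route through this so that a seed
# fixes outputs bit-exactly without clobbering the session RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, staying inside 32-bit
# integer range. Used to give per-fold / per-slide streams that are stable
# under reordering of unrelated work.
child_seed <- function(seed, index) {
  (as.integer(seed) * 1103L + as.integer(index) * 12821L) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fusionmil <- function(...) stop(..., call. = FALSE)
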