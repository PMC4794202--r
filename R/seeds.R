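#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded helpers never perturb global random-number streams.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps (master seed, stage label, unit index) to a
#' 31-bit integer seed via a splitmix-style integer hash, so that every
#' pipeline stage and every subject/replicate gets its own independent
#' stream and no global random state is shared across stages.
#'
#' @param master Master integer seed.
#' @param stage Character stage label (e.g. `"simulate"`).
#' @param index Optional unit index (subject, replicate); default 0.
#' @return An integer in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "simulate", 3)
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(length(master) == 1L, length(stage) == 1L, length(index) == 1L)
  h <- (as.double(master) %% 2147483647) + 1
  for (code in c(utf8ToInt(as.character(stage)), 257, as.integer(index) + 1L)) {
    # 31-bit multiplicative mix; constants are odd primes, arithmetic stays
    # below 2^53 so the double computation is exact
    h <- (h * 48271 + code * 16807 + 11) %% 2147483647
    h <- (h * 69621 + 7) %% 2147483647
  }
  as.integer(h)
}
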