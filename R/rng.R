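#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed`, so library code never disturbs the
#' caller's random stream.
#'
#' @param seed integer master seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    if (is.null(old)) {
      # restore the session default kind too; set.seed(kind=) is sticky
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Evaluate an expression in a named L'Ecuyer-CMRG substream
#'
#' Substream `index` of master seed `seed` is selected by advancing the
#' CMRG stream generator, giving independent, order-free random streams
#' for subjects, permutations and bootstrap draws.
#'
#' @param seed integer master seed.
#' @param index non-negative integer substream index.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(seed, index, expr) {
  stopifnot(index >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    if (is.null(old)) {
      # restore the session default kind too; set.seed(kind=) is sticky
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  if (index > 0) for (k in seq_len(index)) s <- parallel::nextRNGStream(s)
  assign(".Random.seed", s, envir = globalenv())
  expr
}
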