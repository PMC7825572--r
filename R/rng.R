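#' Derive a reproducible sub-seed from a root seed and a stage name
#'
#' A single root seed plus stable stage names gives each stochastic stage its
#' own reproducible stream, so unrelated changes to one stage never perturb
#' another.  The derivation is a plain 31-ary polynomial string hash folded
#' into the root seed, reduced modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer root seed.
#' @param name character scalar naming the substream (e.g. "permutation/CK").
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

#' Evaluate an expression under a local, restored RNG state
#'
#' Sets the seed if one is given, runs `expr`, and restores the caller's
#' `.Random.seed` afterwards, so library code never clobbers user streams.
#'
#' @param seed integer seed or NULL (use the current global stream).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
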