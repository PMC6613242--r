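#' Derive a stage-specific random seed from a global seed
#'
#' A single run-level seed is mapped to independent per-stage seeds by a
#' deterministic string hash, so adding a stage to a pipeline never perturbs
#' the random draws of earlier stages.
#'
#' @param seed integer global seed.
#' @param key character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (c in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
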