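#' Derive a reproducible sub-stream seed from a master seed
#'
#' Counter-based mixing used everywhere the package needs independent but
#' reproducible random streams (per subject, per node pair).  The result is
#' always a valid 32-bit seed in 1..2147483646.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the sub-stream (subject number,
#'   source node, target node, ...).
#' @return A single integer seed.
#' @examples
#' derive_seed(42, 3, 1) != derive_seed(42, 1, 3)
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- as.double(master) %% m
  for (k in idx) {
    # LCG-style mixing; all intermediates stay exactly representable
    s <- (s * 48271 + (as.double(k) %% m) * 16807 + 12345) %% m
  }
  as.integer(s %% (m - 1)) + 1L
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
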