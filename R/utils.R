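# Internal helpers: scoped RNG and named seed substreams.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a deterministic substream seed from a root seed and a stage name
#'
#' All randomness in the pipeline flows from one root seed via named
#' substreams, so stages can be rerun independently and still compose.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
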