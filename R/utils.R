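# Internal utilities shared across the pipeline stages.

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded package functions never disturb the session stream.  A `NULL`
#' seed evaluates `code` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible stage seed from a master seed
#'
#' Mixes a master seed with a text tag so that every randomised stage of the
#' pipeline consumes its own documented stream.  The result always fits a
#' 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the stage (e.g. `"pclrc/M+/C+"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

#' Tucker congruence between two loading vectors
#'
#' Cosine similarity `|<a, b>| / (||a|| ||b||)`, the standard score for
#' agreement between component loadings up to sign.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A value in `[0, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(length(a) == length(b))
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# Stops with a stage-prefixed message; used by run_pipeline error contracts.
stage_stop <- function(stage, ...) {
  stop(sprintf("[stage %s] %s", stage, paste0(...)), call. = FALSE)
}
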