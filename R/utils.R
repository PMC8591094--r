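# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Trim leading/trailing whitespace from a character vector
#' @noRd
str_trim <- function(x) gsub("^\\s+|\\s+$", "", x)

#' Stop with a formatted message, without the call
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Warn with a formatted message, without the call
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Run an expression with a locally set RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed; stays below 2^31
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(seed) %% 2000000L) * 1000L + h
}
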