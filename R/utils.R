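# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a fixed RNG seed, restoring the global RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_scalar_count <- function(x) {
  is_scalar_number(x) && x >= 0 && abs(x - round(x)) < 1e-9
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stopf("%s must be a single string", what)
  invisible(x)
}

# C-locale lexicographic order, independent of the session locale
lex_order <- function(x) order(x, method = "radix")

is_punct_token <- function(token) grepl("^[[:punct:]]+$", token)
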