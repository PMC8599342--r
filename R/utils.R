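#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so simulation functions are
#' deterministic without clobbering the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Derive a stream-specific seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 7919) %% 2147483647)
}

stop_usage <- function(...) {
  stop(structure(class = c("atacscreen_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == floor(x)
is_rate <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
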