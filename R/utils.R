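# input validation helpers; kept terse on purpose

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(sprintf(...), call. = call.)
}

check_prob <- function(p, name, allow_one = FALSE) {
  stop_if(!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 ||
            (if (allow_one) p > 1 else p >= 1),
          "`%s` must be a probability in [0, %s), got %s",
          name, if (allow_one) "1]" else "1", format(p))
  invisible(p)
}

check_count <- function(n, name, min = 1L) {
  stop_if(!is.numeric(n) || length(n) != 1L || is.na(n) || n < min ||
            n != round(n),
          "`%s` must be an integer >= %d", name, min)
  as.integer(n)
}

check_pos <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0,
          "`%s` must be a positive number", name)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Components of the pipeline (task generation, weight initialization, noise,
#' decoder folds) draw their randomness from sub-seeds expanded from one master
#' seed, so any single artifact can be regenerated in isolation. Kept below
#' 2^31 so the result is a valid R integer seed.
#'
#' @param seed master integer seed
#' @param offset integer component offset
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 16807) %%
               2147483647)
}

sigmoid <- function(z) plogis(z)

# null-default
`%||%` <- function(a, b) if (is.null(a)) b else a
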