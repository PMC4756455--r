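# internal helpers

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_number <- function(x, field, lower = -Inf, upper = Inf,
                          integer = FALSE, allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0L) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single non-missing number")
  if (integer && x != round(x))
    stop_field(field, "must be an integer")
  if (x < lower || x > upper)
    stop_field(field, sprintf("must be in [%s, %s]", lower, upper))
  invisible(x)
}

#' Derive a labelled child seed from a master seed
#'
#' Expands one master seed into independent per-stage seeds so that every
#' stochastic stage of an analysis is reproducible from a single integer.
#' The result is always a valid R integer (below 2^31).
#'
#' @param seed master seed, a single integer.
#' @param label character label naming the stage or replicate.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(42, "simulate")
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
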