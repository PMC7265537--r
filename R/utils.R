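# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in genomics
#' reports conventionally round half up. Used wherever a rounded percentage
#' is reported alongside the unrounded value.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("bqpipe_invalid_argument", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("bqpipe_parse_error", "error")))
}

# Deterministic seed fan-out: derive a per-stage seed from a master seed.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}
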