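#' Hill function
#'
#' Saturating Hill response \code{x^n / (km^n + x^n)}, the basic
#' signal-transduction and growth/death transfer function of the model.
#'
#' @param x input (>= 0); values <= 0 return 0.
#' @param km half-saturation constant (> 0).
#' @param n Hill exponent (>= 1).
#' @return numeric in [0, 1).
#' @export
hillFn <- function(x, km, n = 1) {
  stopifnot(km > 0, n >= 1)
  ifelse(x <= 0, 0, x^n / (km^n + x^n))
}

.assertScalarNum <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop(sprintf("'%s' must be a finite numeric scalar >= %g", name, lower),
         call. = FALSE)
  invisible(x)
}

.assertNonNeg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", name), call. = FALSE)
  invisible(x)
}

## internal: resolve a seed to a valid integer for set.seed
.resolveSeed <- function(seed) {
  if (is.null(seed)) seed <- 0
  as.integer(seed %% .Machine$integer.max)
}
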