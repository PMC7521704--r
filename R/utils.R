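# Internal numeric helpers.

# Elementwise log(exp(a) + exp(b)) without overflow; -Inf inputs are
# treated as log(0).
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  both_ninf <- is.infinite(m) & m < 0
  out[both_ninf] <- -Inf
  out
}

# log(1 - exp(x)) for x <= 0, stable near 0 and -Inf.
log1mexp <- function(x) {
  stopifnot(all(x <= 0))
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

stop_tilefs <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "tilefs_error")))
}
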