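# Internal numerical helpers.

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# single check that a numeric argument is finite and positive
check_positive <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)) || any(x <= 0),
          sprintf("`%s` must be finite and > 0", name))
  invisible(x)
}

# derive reproducible sub-seeds from one root seed (kept below 2^31)
split_seed <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}
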