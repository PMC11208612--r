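# internal helpers shared across modules

logit <- function(x) stats::qlogis(x)
invlogit <- function(x) stats::plogis(x)

# multinomial-logit with cell 1 as reference: eta has length J - 1
softmax1 <- function(eta) {
  e <- exp(c(0, eta) - max(0, eta))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msord <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_upper) all(x < 1) else all(x <= 1)
  if (!all(is.finite(x)) || !lo_ok || !hi_ok)
    stop_msord(sprintf("'%s' must lie in %s0, 1%s", name,
                       if (open_lower) "(" else "[",
                       if (open_upper) ")" else "]"))
  invisible(x)
}

# deterministic child seeds below 2^31 derived from one user seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483399)
}
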