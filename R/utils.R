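# internal condition helpers: argument errors (bad user input) vs capability
# errors (request exceeds a documented cap) get distinct classes so callers
# (and the CLI exit-code mapping) can tell them apart.

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = c("uxp_argument_error", "uxp_error"), ...)
}

abort_capability <- function(msg, ...) {
  rlang::abort(msg, class = c("uxp_capability_error", "uxp_error"), ...)
}

abort_internal <- function(msg, ...) {
  rlang::abort(msg, class = c("uxp_internal_error", "uxp_error"), ...)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    abort_argument(sprintf("`%s` must be a single finite number, not %s.",
                           name, paste(deparse(x), collapse = "")))
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_argument(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# tau^k / k! for k = 1..nt, built iteratively so every series evaluator in the
# package shares the identical floating-point path (the degenerate-schedule
# reduction to the Taylor series is then exact, not just close).
tau_power_terms <- function(tau, nt) {
  out <- numeric(nt)
  term <- 1
  for (k in seq_len(nt)) {
    term <- term * tau / k
    out[k] <- term
  }
  out
}
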