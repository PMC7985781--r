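#' Uniformly sampled record of past function values
#'
#' The baseline alternative to direct derivative sensing: the signal alone
#' is recorded at the sampling period `T`, most recent first, at times
#' `t0, t0 - T, t0 - 2T, ...`. An n-th derivative estimate of n-th-order
#' accuracy consumes the `2n` most recent samples, so it is only available
#' a time lag `(2n - 1) * T` after the oldest sample it needs.
#'
#' @param values numeric vector of samples, most recent (at `t0`) first.
#' @param period positive sampling period `T`.
#' @param t0 time of the most recent sample.
#' @return An object of class `uxp_record`.
#' @examples
#' rec <- sampled_record(exp(-(0:5) * 0.01), period = 0.01)
#' backward_fd_derivative(rec, 2)
#' @export
sampled_record <- function(values, period, t0 = 0) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    abort_argument("`values` must be a numeric vector of at least 2 samples.")
  }
  period <- check_scalar_number(period, "period")
  if (period <= 0) abort_argument("`period` must be positive.")
  t0 <- check_scalar_number(t0, "t0")
  structure(list(values = as.numeric(values), period = period, t0 = t0),
            class = "uxp_record")
}

#' @export
print.uxp_record <- function(x, ...) {
  cat("<sampled record> ", length(x$values), " samples, period T = ",
      format(x$period), ", most recent at t0 = ", format(x$t0), "\n", sep = "")
  invisible(x)
}

# weights w_j (j = 0..2n-1, most recent first) such that
# sum_j w_j f(t0 - jT) ~ T^n f^(n)(t0) with n-th-order accuracy:
# moment conditions sum_j w_j (-j)^m / m! = delta_{mn}, m = 0..2n-1,
# solved from the Vandermonde system at runtime.
backward_fd_weights <- function(n) {
  npts <- 2L * n
  j <- 0:(npts - 1L)
  A <- outer(0:(npts - 1L), j, function(m, j) (-j)^m / factorial(m))
  b <- numeric(npts)
  b[n + 1L] <- 1
  drop(solve(A, b))
}

#' Backward finite-difference derivative estimate
#'
#' Estimates `f^(n)(t0)` from the `2n` most recent samples of a
#' [sampled_record()] using the n-th-order-accurate backward stencil. This
#' is the latency-bearing baseline: the estimate cannot exist before the
#' oldest of its samples, i.e. before a lag of `(2n - 1) * T`.
#'
#' @param record a [sampled_record()].
#' @param n derivative order.
#' @return A single number.
#' @export
backward_fd_derivative <- function(record, n) {
  stopifnot(inherits(record, "uxp_record"))
  n <- check_count(n, "n")
  need <- 2L * n
  if (length(record$values) < need) {
    abort_argument(sprintf(
      "order-%d backward difference needs 2n = %d samples, record has %d.",
      n, need, length(record$values)))
  }
  w <- backward_fd_weights(n)
  sum(w * record$values[seq_len(need)]) / record$period^n
}

#' Taylor prediction from backward finite-difference derivatives
#'
#' The baseline predictor: derivatives `1..nt` are estimated from the
#' record by backward finite differences (order `k` from the `2k` most
#' recent samples) and fed to the Taylor polynomial. The result carries
#' the number of samples consumed (`2 * nt`) and the implied acquisition
#' lag (`(2 * nt - 1) * T`) so the latency/accuracy trade-off against
#' direct derivative sensing is explicit.
#'
#' @param record a [sampled_record()].
#' @param tau time increment ahead of `t0`.
#' @param nt truncation order.
#' @return A one-row tibble with columns `scheme`, `nt`, `tau`, `value`,
#'   `samples_used`, `acquisition_lag`.
#' @export
backward_fd_predict <- function(record, tau, nt) {
  stopifnot(inherits(record, "uxp_record"))
  nt <- check_count(nt, "nt")
  need <- 2L * nt
  if (length(record$values) < need) {
    abort_argument(sprintf(
      "order-%d prediction needs 2n = %d samples, record has %d.",
      nt, need, length(record$values)))
  }
  derivs <- c(record$values[1L],
              vapply(seq_len(nt), function(k) backward_fd_derivative(record, k),
                     numeric(1)))
  out <- taylor_predict(derivs, tau, nt)
  out$scheme <- "backward-FD"
  out$samples_used <- need
  out$acquisition_lag <- (need - 1L) * record$period
  out
}
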