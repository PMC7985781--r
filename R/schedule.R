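#' Detection schedules for unsynchronized derivative observations
#'
#' A detection schedule records the base time `t0` at which the signal value
#' itself is known and the times `t1, ..., tN` at which the successive
#' derivatives (order 1 to N) were detected. Times are dimensionless
#' (normalized to an arbitrary time constant); they need not be ordered or
#' distinct.
#'
#' @param t0 base time at which the function value is observed.
#' @param times numeric vector; `times[n]` is the detection time of the n-th
#'   derivative.
#' @return An object of class `uxp_schedule`.
#' @seealso [uniform_lag_schedule()], [max_gap()]
#' @examples
#' s <- detection_schedule(t0 = 0.3, times = c(0.1, 0.05, -0.2))
#' max_gap(s)
#' @export
detection_schedule <- function(t0, times) {
  t0 <- check_scalar_number(t0, "t0")
  if (!is.numeric(times) || length(times) < 1L || anyNA(times) || !all(is.finite(times))) {
    abort_argument("`times` must be a nonempty vector of finite detection times.")
  }
  structure(
    list(t0 = t0, times = as.numeric(times), N = length(times)),
    class = "uxp_schedule"
  )
}

#' Uniform-lag detection schedule
#'
#' The schedule in which the n-th derivative is detected progressively
#' earlier, at `tn = t0 - n * lag`. This is the most unfavorable regular
#' schedule for prediction (every derivative is as stale as its order
#' allows) and the one for which the expansion coefficients factor into
#' exact rationals times powers of the lag.
#'
#' @param t0 base time.
#' @param lag positive lag `t` between successive detection times.
#' @param N number of derivative orders covered.
#' @return An object of class `uxp_uniform_schedule` (also a `uxp_schedule`).
#' @examples
#' uniform_lag_schedule(t0 = 0, lag = 0.01, N = 4)
#' @export
uniform_lag_schedule <- function(t0, lag, N) {
  t0 <- check_scalar_number(t0, "t0")
  lag <- check_scalar_number(lag, "lag")
  if (lag <= 0) abort_argument("`lag` must be positive.")
  N <- check_count(N, "N")
  s <- detection_schedule(t0, t0 - seq_len(N) * lag)
  s$lag <- lag
  class(s) <- c("uxp_uniform_schedule", class(s))
  s
}

#' Maximum gap between successive detection times
#'
#' The largest absolute difference between the detection times of two
#' successive derivative orders, with the base time `t0` counting as the
#' zeroth element. This single number controls how far the unsynchronized
#' expansion's truncation error departs from the Taylor series': the error
#' statements for the uniform-lag schedule carry over to any schedule whose
#' `max_gap` does not exceed the uniform lag.
#'
#' @param schedule a [detection_schedule()].
#' @return A single nonnegative number.
#' @export
max_gap <- function(schedule) {
  stopifnot(inherits(schedule, "uxp_schedule"))
  max(abs(diff(c(schedule$t0, schedule$times))))
}

#' @export
print.uxp_schedule <- function(x, ...) {
  cat("<detection schedule> t0 = ", format(x$t0), ", N = ", x$N, "\n", sep = "")
  cat("  times: ", paste(format(x$times), collapse = ", "), "\n", sep = "")
  cat("  max gap: ", format(max_gap(x)), "\n", sep = "")
  invisible(x)
}

#' @export
print.uxp_uniform_schedule <- function(x, ...) {
  cat("<uniform-lag schedule> t0 = ", format(x$t0), ", lag = ", format(x$lag),
      ", N = ", x$N, "\n", sep = "")
  invisible(x)
}

#' Read a detection schedule from JSON
#'
#' Accepts either `{"t0": ..., "times": [...]}` (arbitrary schedule) or
#' `{"t0": ..., "lag": ..., "N": ...}` (uniform-lag schedule).
#'
#' @param path path to a JSON file.
#' @return A [detection_schedule()] or [uniform_lag_schedule()].
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$times)) {
    detection_schedule(x$t0, x$times)
  } else if (!is.null(x$lag) && !is.null(x$N)) {
    uniform_lag_schedule(x$t0, x$lag, x$N)
  } else {
    abort_argument("schedule JSON must supply either `times` or `lag` and `N`.")
  }
}

#' Write a detection schedule to JSON
#'
#' @param schedule a [detection_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "uxp_schedule"))
  x <- if (inherits(schedule, "uxp_uniform_schedule")) {
    list(t0 = schedule$t0, lag = schedule$lag, N = schedule$N)
  } else {
    list(t0 = schedule$t0, times = schedule$times)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}
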