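#' Truncation error of a series prediction
#'
#' Signed truncation error `exact - predicted` for the unsynchronized
#' expansion on a uniform-lag schedule (scheme `"U"`) or the Taylor series
#' (scheme `"Taylor"`), with derivative values taken exactly from the test
#' trajectory. The `"U"` scheme with `lag = 0` is evaluated through the
#' same code path as `"Taylor"` and is identical to it.
#'
#' @param fn a [test_function()].
#' @param t0 base time.
#' @param lag uniform detection lag `t >= 0` (ignored by scheme `"Taylor"`).
#' @param tau positive time increment.
#' @param nt truncation order.
#' @param scheme `"U"` or `"Taylor"`.
#' @return A single signed number, `fn(t0 + tau)` minus the truncated-series
#'   prediction.
#' @examples
#' truncation_error(test_function("exp"), 0, lag = 0, tau = 0.1, nt = 1,
#'                  scheme = "Taylor") # exp(0.1) - 1.1
#' @export
truncation_error <- function(fn, t0, lag, tau, nt, scheme = c("U", "Taylor")) {
  stopifnot(inherits(fn, "uxp_trajectory"))
  scheme <- match.arg(scheme)
  t0 <- check_scalar_number(t0, "t0")
  tau <- check_scalar_number(tau, "tau")
  if (tau <= 0) abort_argument("`tau` must be positive.")
  nt <- check_count(nt, "nt")
  if (scheme == "Taylor") lag <- 0
  lag <- check_scalar_number(lag, "lag")
  if (lag < 0) abort_argument("`lag` must be nonnegative.")
  exact <- fn$value(t0 + tau)
  pred <- if (scheme == "Taylor" || lag == 0) {
    derivs <- vapply(0:nt, function(k) fn$deriv(t0, k), numeric(1))
    taylor_predict(derivs, tau, nt)$value
  } else {
    sched <- uniform_lag_schedule(t0, lag, nt)
    u_predict_uniform(exact_observations(fn, sched), tau, nt, lag = lag)$value
  }
  exact - pred
}

#' Truncation-error curve over a grid of increments
#'
#' Evaluates [truncation_error()] over a grid of `tau` values, for one or
#' both schemes, returning a tidy curve suitable for plotting on a log
#' scale. Two grid regimes are useful: a wide logarithmic grid (overview)
#' and a dense linear grid on a short range (detail near `tau ~ lag`).
#'
#' @inheritParams truncation_error
#' @param tau_grid strictly increasing vector of positive increments.
#' @param schemes character vector, subset of `c("U", "Taylor")`.
#' @return A tibble with columns `fn`, `t0`, `t` (the lag; 0 for Taylor),
#'   `nt`, `scheme`, `tau`, `error`, of class `uxp_error_curve`.
#' @examples
#' error_curve(test_function("exp"), 0, lag = 0.01, nt = 2,
#'             tau_grid = c(0.005, 0.01, 0.05))
#' @export
error_curve <- function(fn, t0, lag, nt, tau_grid, schemes = c("U", "Taylor")) {
  stopifnot(inherits(fn, "uxp_trajectory"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (!is.numeric(tau_grid) || length(tau_grid) < 1L || any(tau_grid <= 0) ||
      is.unsorted(tau_grid, strictly = TRUE)) {
    abort_argument("`tau_grid` must be a strictly increasing vector of positive increments.")
  }
  out <- purrr::map_dfr(schemes, function(sch) {
    errs <- vapply(tau_grid, function(tau)
      truncation_error(fn, t0, lag, tau, nt, sch), numeric(1))
    tibble::tibble(
      fn = fn$name, t0 = t0, t = if (sch == "Taylor") 0 else lag,
      nt = as.integer(nt), scheme = sch, tau = tau_grid, error = errs)
  })
  structure(out, class = c("uxp_error_curve", class(out)))
}

#' Log-spaced and linear increment grids
#'
#' Convenience grids for the two error-curve regimes: `tau_grid_log()`
#' gives log-spaced points for the wide overview, `tau_grid_linear()`
#' dense linear points for the short-range detail.
#'
#' @param from,to grid range (positive).
#' @param n number of points.
#' @return A strictly increasing numeric vector.
#' @export
tau_grid_log <- function(from = 1e-3, to = 1, n = 60) {
  exp(seq(log(from), log(to), length.out = n))
}

#' @rdname tau_grid_log
#' @export
tau_grid_linear <- function(from, to, n = 200) {
  seq(from, to, length.out = n)
}

#' Maximum absolute error over an increment range
#'
#' @param curve an [error_curve()].
#' @param range length-2 numeric interval of `tau` values (inclusive).
#' @return The maximum of `|error|` over grid points inside `range`.
#' @export
max_abs_error <- function(curve, range = c(0, Inf)) {
  stopifnot(inherits(curve, "uxp_error_curve"))
  if (!is.numeric(range) || length(range) != 2L || range[1] > range[2]) {
    abort_argument("`range` must be a length-2 interval c(lo, hi).")
  }
  sel <- curve$tau >= range[1] & curve$tau <= range[2]
  if (!any(sel)) abort_argument("`range` does not intersect the curve's tau grid.")
  max(abs(curve$error[sel]))
}

#' Write an error curve to CSV
#'
#' @param curve an [error_curve()] (curves may be row-bound first).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_error_curve_csv <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  out <- dplyr::mutate(curve,
                       tau = sprintf("%.17g", .data$tau),
                       error = sprintf("%.17g", .data$error))
  readr::write_csv(out, path)
  invisible(path)
}

#' Plot truncation-error curves
#'
#' Absolute truncation error against the increment `tau` on log-log axes,
#' one colour per truncation order, solid for the unsynchronized expansion
#' and dashed for the Taylor reference — the conventional layout for
#' comparing the two schemes across lags.
#'
#' @param object an [error_curve()] (row-bind several for a multi-panel set).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.uxp_error_curve <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       abs_error = abs(.data$error),
                       order = factor(.data$nt),
                       lag_lab = sprintf("t = %g", .data$t))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau, y = .data$abs_error,
                                    colour = .data$order,
                                    linetype = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~lag_lab) +
    ggplot2::labs(x = expression(tau), y = "|truncation error|",
                  colour = "order", linetype = "scheme") +
    ggplot2::theme_minimal()
}
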