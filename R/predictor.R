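#' Bundle unsynchronized derivative observations
#'
#' Collects the base value `f(t0)` and one observation of each derivative
#' order `1..N`, each at its own detection time. Orders must be contiguous
#' starting at 1 (the expansion consumes every order up to truncation);
#' detection times need not be ordered or distinct.
#'
#' @param data a data frame with columns `n` (order), `t` (detection time)
#'   and `value` (observed derivative value).
#' @param t0 base time.
#' @param f0 observed function value at `t0`.
#' @return An object of class `uxp_observations`.
#' @examples
#' obs <- derivative_observations(
#'   data.frame(n = 1:3, t = c(-0.01, -0.02, -0.03), value = exp(c(-0.01, -0.02, -0.03))),
#'   t0 = 0, f0 = 1)
#' u_predict(obs, tau = 0.1, nt = 3)
#' @export
derivative_observations <- function(data, t0, f0) {
  if (!is.data.frame(data) || !all(c("n", "t", "value") %in% names(data))) {
    abort_argument("`data` must be a data frame with columns `n`, `t`, `value`.")
  }
  t0 <- check_scalar_number(t0, "t0")
  f0 <- check_scalar_number(f0, "f0")
  data <- tibble::as_tibble(data)[c("n", "t", "value")]
  data <- dplyr::arrange(data, .data$n)
  N <- nrow(data)
  if (N < 1L || !identical(as.integer(data$n), seq_len(N))) {
    abort_argument("observations must cover contiguous orders 1..N with exactly one per order.")
  }
  if (anyNA(data$t) || anyNA(data$value) || !all(is.finite(data$t)) || !all(is.finite(data$value))) {
    abort_argument("observation times and values must be finite.")
  }
  structure(list(t0 = t0, f0 = f0, data = data, N = N), class = "uxp_observations")
}

#' @export
print.uxp_observations <- function(x, ...) {
  cat("<derivative observations> t0 = ", format(x$t0), ", f(t0) = ", format(x$f0),
      ", N = ", x$N, "\n", sep = "")
  print(x$data)
  invisible(x)
}

schedule_of <- function(obs) detection_schedule(obs$t0, obs$data$t)

prediction_row <- function(scheme, nt, tau, value) {
  tibble::tibble(scheme = scheme, nt = as.integer(nt), tau = tau, value = value)
}

#' Truncated Taylor prediction
#'
#' Evaluates the Taylor polynomial
#' `f(t0) + sum_{k=1}^{nt} f^(k)(t0) tau^k / k!` from synchronized
#' derivative values, the reference scheme against which the
#' unsynchronized expansion is compared.
#'
#' @param derivatives numeric vector `c(f(t0), f'(t0), ..., f^(nt)(t0))`
#'   (length at least `nt + 1`).
#' @param tau time increment ahead of `t0`.
#' @param nt truncation order (defaults to `length(derivatives) - 1`).
#' @return A one-row tibble with columns `scheme`, `nt`, `tau`, `value`.
#' @examples
#' taylor_predict(rep(1, 5), tau = 0.1) # exp about 0, nt = 4
#' @export
taylor_predict <- function(derivatives, tau, nt = length(derivatives) - 1L) {
  if (!is.numeric(derivatives) || anyNA(derivatives)) {
    abort_argument("`derivatives` must be a numeric vector without NA.")
  }
  tau <- check_scalar_number(tau, "tau")
  nt <- check_count(nt, "nt")
  if (length(derivatives) < nt + 1L) {
    abort_argument(sprintf(
      "`derivatives` must supply f(t0) and the first %d derivatives (%d values), got %d.",
      nt, nt + 1L, length(derivatives)))
  }
  tt <- tau_power_terms(tau, nt)
  value <- derivatives[1L]
  for (k in seq_len(nt)) value <- value + derivatives[k + 1L] * tt[k]
  prediction_row("Taylor", nt, tau, value)
}

#' Unsynchronized-expansion prediction (arbitrary schedule)
#'
#' Evaluates the truncated unsynchronized expansion
#' `f(t0) + sum_{n=1}^{nt} f^(n)(tn) * sum_{k=1}^{n} tau^k/k! p_nk`,
#' with the coefficients `p_nk` computed from the detection schedule
#' embedded in `obs`. When every detection time equals `t0` this reduces
#' exactly to [taylor_predict()].
#'
#' @param obs a [derivative_observations()] set.
#' @param tau time increment ahead of `t0`.
#' @param nt truncation order, at most `obs$N`.
#' @return A one-row tibble with columns `scheme`, `nt`, `tau`, `value`.
#' @export
u_predict <- function(obs, tau, nt = obs$N) {
  stopifnot(inherits(obs, "uxp_observations"))
  tau <- check_scalar_number(tau, "tau")
  nt <- check_count(nt, "nt")
  if (nt > obs$N) {
    abort_argument(sprintf("`nt` = %d exceeds the number of observed orders N = %d.",
                           nt, obs$N))
  }
  sched <- schedule_of(obs)
  tt <- tau_power_terms(tau, nt)
  value <- obs$f0
  for (n in seq_len(nt)) {
    inner <- sum(tt[seq_len(n)] *
                   vapply(seq_len(n), function(k) p_coefficient(sched, n, k), numeric(1)))
    value <- value + obs$data$value[n] * inner
  }
  prediction_row("U", nt, tau, value)
}

#' Unsynchronized-expansion prediction (uniform-lag schedule)
#'
#' Specialized evaluator for observations on the uniform-lag schedule
#' `tn = t0 - n * lag`, using the exact rational coefficients `c_nk` and
#' powers of the lag. The observation times are checked against the
#' uniform-lag pattern (absolute tolerance 1e-12).
#'
#' @inheritParams u_predict
#' @param lag the uniform lag `t > 0`; inferred from the first observation
#'   time when omitted.
#' @return A one-row tibble with columns `scheme`, `nt`, `tau`, `value`.
#' @export
u_predict_uniform <- function(obs, tau, nt = obs$N, lag = NULL) {
  stopifnot(inherits(obs, "uxp_observations"))
  tau <- check_scalar_number(tau, "tau")
  nt <- check_count(nt, "nt")
  if (nt > obs$N) {
    abort_argument(sprintf("`nt` = %d exceeds the number of observed orders N = %d.",
                           nt, obs$N))
  }
  if (is.null(lag)) lag <- obs$t0 - obs$data$t[1L]
  lag <- check_scalar_number(lag, "lag")
  if (lag <= 0) abort_argument("`lag` must be positive.")
  expected <- obs$t0 - seq_len(obs$N) * lag
  dev <- max(abs(obs$data$t - expected))
  if (dev > 1e-12) {
    abort_argument(sprintf(
      "observation times deviate from the uniform-lag pattern tn = t0 - n*lag by %.3g (> 1e-12).",
      dev))
  }
  tt <- tau_power_terms(tau, nt)
  value <- obs$f0
  for (n in seq_len(nt)) {
    inner <- sum(vapply(seq_len(n), function(k) {
      tt[k] * q_dbl(c_coefficient(n, k)) * lag^(n - k)
    }, numeric(1)))
    value <- value + obs$data$value[n] * inner
  }
  prediction_row("U", nt, tau, value)
}

#' Read derivative observations from JSON or CSV
#'
#' JSON layout: `{"t0": ..., "f0": ..., "observations": [{"n": 1, "t": ...,
#' "value": ...}, ...]}`. CSV layout: columns `n`, `t`, `value`, with `n = 0`
#' carrying the base time and value.
#'
#' @param path input path; format chosen by extension (`.json` else CSV).
#' @return A [derivative_observations()] set.
#' @export
read_observations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$t0) || is.null(x$f0) || is.null(x$observations)) {
      abort_argument("observation JSON must supply `t0`, `f0` and `observations`.")
    }
    derivative_observations(tibble::as_tibble(x$observations), t0 = x$t0, f0 = x$f0)
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE)
    base <- dplyr::filter(x, .data$n == 0L)
    if (nrow(base) != 1L) {
      abort_argument("observation CSV must contain exactly one n = 0 row with t0 and f(t0).")
    }
    derivative_observations(dplyr::filter(x, .data$n > 0L),
                            t0 = base$t[1L], f0 = base$value[1L])
  }
}

#' Write derivative observations to JSON
#'
#' @param obs a [derivative_observations()] set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations_json <- function(obs, path) {
  stopifnot(inherits(obs, "uxp_observations"))
  jsonlite::write_json(
    list(t0 = obs$t0, f0 = obs$f0, observations = obs$data),
    path, auto_unbox = TRUE, digits = 17, dataframe = "rows")
  invisible(path)
}

#' Write a prediction to JSON
#'
#' @param prediction a one-row prediction tibble from [taylor_predict()],
#'   [u_predict()], [u_predict_uniform()] or [backward_fd_predict()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(prediction, path) {
  stopifnot(is.data.frame(prediction), nrow(prediction) == 1L)
  jsonlite::write_json(as.list(prediction), path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}
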