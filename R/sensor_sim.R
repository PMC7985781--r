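# Synthetic sensor-like observation streams: a known trajectory sampled the
# way unsynchronized receptors would report it — each derivative order at
# its own (possibly jittered) detection time, optionally with additive
# Gaussian observation noise.

#' Schedule specification for a sensor stream
#'
#' Describes how detection times relate to each rolling base time `t0`:
#' `"uniform"` places order n at `t0 - n * lag`; `"jittered"` adds an
#' independent uniform perturbation of total width `jitter` to each
#' detection time (so successive gaps never exceed `lag + jitter`);
#' `"explicit"` uses fixed offsets, order n at `t0 - offsets[n]`.
#'
#' @param kind `"uniform"`, `"jittered"` or `"explicit"`.
#' @param lag base lag between successive orders (uniform, jittered).
#' @param N number of derivative orders observed.
#' @param jitter total width of the uniform jitter (jittered only).
#' @param offsets numeric vector of offsets from `t0` (explicit only).
#' @return An object of class `uxp_stream_schedule`.
#' @export
stream_schedule <- function(kind = c("uniform", "jittered", "explicit"),
                            lag = NULL, N = NULL, jitter = 0, offsets = NULL) {
  kind <- match.arg(kind)
  if (kind == "explicit") {
    if (!is.numeric(offsets) || length(offsets) < 1L) {
      abort_argument("`explicit` schedules need a numeric `offsets` vector.")
    }
    N <- length(offsets)
  } else {
    lag <- check_scalar_number(lag, "lag")
    if (lag <= 0) abort_argument("`lag` must be positive.")
    N <- check_count(N, "N")
    if (kind == "jittered") {
      jitter <- check_scalar_number(jitter, "jitter")
      if (jitter < 0) abort_argument("`jitter` must be nonnegative.")
    }
  }
  structure(list(kind = kind, lag = lag, N = N, jitter = jitter, offsets = offsets),
            class = "uxp_stream_schedule")
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic unsynchronized observation stream
#'
#' Emulates a bank of sensors reporting a trajectory and its derivatives at
#' staggered times: for each base time in `t0`, the order-n derivative is
#' observed at the time dictated by `schedule` and perturbed by additive
#' i.i.d. Gaussian noise of standard deviation `sigma` (applied to the
#' observed values, including the order-0 value). With `sigma = 0` every
#' stored value is the trajectory's exact derivative at its stored time.
#' Given the same `seed`, the stream is bit-reproducible.
#'
#' @param fn a [test_function()] trajectory.
#' @param schedule a [stream_schedule()].
#' @param t0 numeric vector of base times (the rolling span).
#' @param sigma nonnegative observation-noise standard deviation.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A tibble with columns `step`, `t0`, `n` (0 = the value itself),
#'   `time`, `value`, of class `uxp_sensor_stream`; the trajectory,
#'   schedule, `sigma` and `seed` ride along as attributes.
#' @examples
#' st <- generate_stream(test_function("exp"),
#'                       stream_schedule("uniform", lag = 0.01, N = 3),
#'                       t0 = seq(0, 0.5, by = 0.1), seed = 1)
#' head(st)
#' @export
generate_stream <- function(fn, schedule, t0, sigma = 0, seed = NULL) {
  stopifnot(inherits(fn, "uxp_trajectory"), inherits(schedule, "uxp_stream_schedule"))
  if (!is.numeric(t0) || length(t0) < 1L) {
    abort_argument("`t0` must be a numeric vector of base times.")
  }
  sigma <- check_scalar_number(sigma, "sigma")
  if (sigma < 0) abort_argument("`sigma` must be nonnegative.")
  N <- schedule$N
  rows <- with_local_seed(seed, {
    purrr::imap_dfr(as.numeric(t0), function(base, step) {
      times <- switch(schedule$kind,
        uniform = base - seq_len(N) * schedule$lag,
        jittered = base - seq_len(N) * schedule$lag +
          stats::runif(N, -schedule$jitter / 2, schedule$jitter / 2),
        explicit = base - schedule$offsets)
      vals <- c(fn$value(base),
                vapply(seq_len(N), function(n) fn$deriv(times[n], n), numeric(1)))
      if (sigma > 0) vals <- vals + stats::rnorm(N + 1L, 0, sigma)
      tibble::tibble(step = step, t0 = base, n = 0:N,
                     time = c(base, times), value = vals)
    })
  })
  structure(rows, class = c("uxp_sensor_stream", class(rows)),
            trajectory = fn, schedule = schedule, sigma = sigma, seed = seed)
}

# rebuild the observation set of one base-time step
stream_observations <- function(stream, step) {
  rows <- stream[stream$step == step, , drop = FALSE]
  base <- rows[rows$n == 0L, ]
  derivative_observations(
    tibble::tibble(n = rows$n[rows$n > 0L], t = rows$time[rows$n > 0L],
                   value = rows$value[rows$n > 0L]),
    t0 = base$t0[1L], f0 = base$value[1L])
}

#' Rolling-horizon prediction experiment on a sensor stream
#'
#' At every base time of the stream, predicts the trajectory `tau` ahead
#' with the unsynchronized expansion truncated at order `nt` and scores the
#' prediction against the true trajectory value. This is the prediction
#' stage of the sensorimotor use case: latency-free extrapolation from
#' whatever staggered observations are in hand; no control loop is closed.
#'
#' @param stream a [generate_stream()] result.
#' @param tau prediction horizon ahead of each base time.
#' @param nt truncation order (at most the stream's number of orders).
#' @return An object of class `uxp_experiment`: per-step records plus an
#'   error summary; see [tidy.uxp_experiment()] and
#'   [glance.uxp_experiment()].
#' @export
rolling_prediction <- function(stream, tau, nt) {
  stopifnot(inherits(stream, "uxp_sensor_stream"))
  tau <- check_scalar_number(tau, "tau")
  nt <- check_count(nt, "nt")
  N <- attr(stream, "schedule")$N
  if (nt > N) {
    abort_argument(sprintf("`nt` = %d exceeds the stream's %d observed orders.", nt, N))
  }
  fn <- attr(stream, "trajectory")
  steps <- unique(stream$step)
  records <- purrr::map_dfr(steps, function(s) {
    obs <- stream_observations(stream, s)
    pred <- u_predict(obs, tau, nt)$value
    truth <- fn$value(obs$t0 + tau)
    tibble::tibble(t0 = obs$t0, tau = tau, truth = truth,
                   prediction = pred, error = truth - pred)
  })
  structure(
    list(records = records,
         tau = tau, nt = nt, trajectory = fn,
         max_abs_error = max(abs(records$error)),
         rms_error = sqrt(mean(records$error^2))),
    class = "uxp_experiment")
}

#' @export
print.uxp_experiment <- function(x, ...) {
  cat("<prediction experiment> ", nrow(x$records), " steps, nt = ", x$nt,
      ", tau = ", format(x$tau), "\n", sep = "")
  cat("  max |error| = ", format(x$max_abs_error),
      ", RMS error = ", format(x$rms_error), "\n", sep = "")
  invisible(x)
}

#' Tidy the per-step records of a prediction experiment
#'
#' @param x a [rolling_prediction()] result.
#' @param ... unused.
#' @return A tibble with columns `t0`, `tau`, `truth`, `prediction`, `error`.
#' @export
tidy.uxp_experiment <- function(x, ...) {
  x$records
}

#' One-row summary of a prediction experiment
#'
#' @param x a [rolling_prediction()] result.
#' @param ... unused.
#' @return A one-row tibble: `steps`, `nt`, `tau`, `max_abs_error`, `rms_error`.
#' @export
glance.uxp_experiment <- function(x, ...) {
  tibble::tibble(steps = nrow(x$records), nt = x$nt, tau = x$tau,
                 max_abs_error = x$max_abs_error, rms_error = x$rms_error)
}

#' Plot predicted against true trajectory values
#'
#' @param object a [rolling_prediction()] result.
#' @param ... unused.
#' @return A ggplot object: truth and prediction over the base times, with
#'   the signed error in a rug of points around zero.
#' @export
autoplot.uxp_experiment <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$records, c("truth", "prediction"),
                             names_to = "series", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t0, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(t[0]), y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a sensor stream as JSON-lines
#'
#' One JSON object per base time, holding the base value and the staggered
#' derivative observations of that step.
#'
#' @param stream a [generate_stream()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stream_jsonl <- function(stream, path) {
  stopifnot(inherits(stream, "uxp_sensor_stream"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in unique(stream$step)) {
    obs <- stream_observations(stream, s)
    writeLines(jsonlite::toJSON(
      list(t0 = obs$t0, f0 = obs$f0, observations = obs$data),
      auto_unbox = TRUE, digits = 17, dataframe = "rows"), con)
  }
  invisible(path)
}

#' Write a prediction experiment to CSV plus a JSON summary
#'
#' @param experiment a [rolling_prediction()] result.
#' @param csv_path path for the per-step records CSV.
#' @param summary_path optional path for a JSON summary.
#' @return `csv_path`, invisibly.
#' @export
write_experiment_csv <- function(experiment, csv_path, summary_path = NULL) {
  stopifnot(inherits(experiment, "uxp_experiment"))
  out <- dplyr::mutate(experiment$records,
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ sprintf("%.17g", .x)))
  readr::write_csv(out, csv_path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(as.list(glance(experiment)), summary_path,
                         auto_unbox = TRUE, digits = 17)
  }
  invisible(csv_path)
}
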