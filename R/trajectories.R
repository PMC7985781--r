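#' Analytic test trajectories with exact derivatives
#'
#' Named smooth test functions with closed-form derivatives of every order,
#' used to probe truncation error and to drive the synthetic sensor-stream
#' generator. Built-ins: `"exp"`, `"sin"`, and `"polynomial"` (with
#' ascending coefficients); `"custom"` accepts user evaluators.
#'
#' @param name one of `"exp"`, `"sin"`, `"polynomial"`, `"custom"`.
#' @param coeffs for `"polynomial"`: numeric vector of coefficients in
#'   ascending powers (`coeffs[1] + coeffs[2] * t + ...`).
#' @param value,deriv for `"custom"`: `value(t)` and `deriv(t, order)`
#'   evaluators (`order >= 1`).
#' @return An object of class `uxp_trajectory` with elements `name`,
#'   `value(t)` and `deriv(t, order)`; `deriv(t, 0)` returns the value.
#' @examples
#' fn <- test_function("sin")
#' fn$deriv(pi / 4, 2) # -sin(pi/4)
#' test_function("polynomial", coeffs = c(2, -1, 3))$value(1.5)
#' @export
test_function <- function(name = c("exp", "sin", "polynomial", "custom"),
                          coeffs = NULL, value = NULL, deriv = NULL) {
  name <- match.arg(name)
  fn <- switch(
    name,
    exp = list(
      value = function(t) exp(t),
      deriv = function(t, order) exp(t)
    ),
    sin = list(
      value = function(t) sin(t),
      # each differentiation shifts the phase by pi/2
      deriv = function(t, order) sin(t + order * pi / 2)
    ),
    polynomial = {
      if (is.null(coeffs) || !is.numeric(coeffs) || length(coeffs) < 1L) {
        abort_argument("`polynomial` needs a numeric `coeffs` vector (ascending powers).")
      }
      force(coeffs)
      list(
        value = function(t) {
          powers <- outer(t, seq_along(coeffs) - 1L, `^`)
          drop(powers %*% coeffs)
        },
        deriv = function(t, order) {
          d <- coeffs
          for (i in seq_len(order)) {
            if (length(d) <= 1L) return(rep(0, length(t)))
            d <- d[-1L] * seq_len(length(d) - 1L)
          }
          powers <- outer(t, seq_along(d) - 1L, `^`)
          drop(powers %*% d)
        }
      )
    },
    custom = {
      if (!is.function(value) || !is.function(deriv)) {
        abort_argument("`custom` needs `value(t)` and `deriv(t, order)` functions.")
      }
      list(value = value, deriv = deriv)
    }
  )
  dv <- fn$deriv
  structure(
    list(name = name,
         value = fn$value,
         deriv = function(t, order) {
           order <- check_count(order, "order", min = 0L)
           if (order == 0L) fn$value(t) else dv(t, order)
         },
         coeffs = coeffs),
    class = "uxp_trajectory")
}

#' @export
print.uxp_trajectory <- function(x, ...) {
  cat("<trajectory> ", x$name, "\n", sep = "")
  if (!is.null(x$coeffs)) {
    cat("  coefficients (ascending): ", paste(format(x$coeffs), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# exact derivative observations of a trajectory on a schedule
exact_observations <- function(fn, schedule) {
  stopifnot(inherits(fn, "uxp_trajectory"), inherits(schedule, "uxp_schedule"))
  derivative_observations(
    tibble::tibble(
      n = seq_len(schedule$N),
      t = schedule$times,
      value = vapply(seq_len(schedule$N),
                     function(n) fn$deriv(schedule$times[n], n), numeric(1))),
    t0 = schedule$t0, f0 = fn$value(schedule$t0))
}
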