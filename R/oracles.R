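# Two independent derivations of the expansion coefficients, used to
# validate the chain-sum implementation (and each other).

#' Coefficient table from monomial exactness
#'
#' Derives the expansion coefficients without the chain-sum formula, by
#' requiring the truncated expansion to be exact on the monomials
#' `f(t) = (t - t0)^m` for `m = 1..n_max`. Matching the coefficient of
#' `tau^k` on both sides gives one triangular linear relation per (m, k)
#' that is solved recursively in m: the diagonal `p_mm = 1` is forced, and
#' each `p_mk` with `k < m` then follows from the already-known lower rows.
#' This route shares no code with [p_coefficient()] and serves as its
#' independent check.
#'
#' @inheritParams coefficient_table
#' @return A tibble with columns `n`, `k`, `p`, of class `uxp_coef_table`.
#' @export
monomial_coefficient_table <- function(schedule, n_max) {
  stopifnot(inherits(schedule, "uxp_schedule"))
  n_max <- check_count(n_max, "n_max")
  if (n_max > schedule$N) {
    abort_argument(sprintf("`n_max` = %d exceeds the schedule length N = %d.",
                           n_max, schedule$N))
  }
  t0 <- schedule$t0
  tn <- schedule$times
  p <- matrix(NA_real_, n_max, n_max)
  for (m in seq_len(n_max)) {
    p[m, m] <- 1
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        # d-th derivative of (t - t0)^m at tn: m!/(m-d)! (tn - t0)^(m-d);
        # exactness on tau^k demands sum_n deriv_n * p_nk = 0 for k < m
        lower <- seq(k, m - 1L)
        deriv <- factorial(m) / factorial(m - lower) * (tn[lower] - t0)^(m - lower)
        rhs <- sum(deriv * p[lower, k])
        if (!is.finite(rhs)) abort_internal("singular monomial system.")
        p[m, k] <- -rhs / factorial(m)
      }
    }
  }
  tab <- tidyr::expand_grid(n = seq_len(n_max), k = seq_len(n_max)) |>
    dplyr::filter(.data$k <= .data$n) |>
    dplyr::mutate(p = p[cbind(.data$n, .data$k)])
  structure(tab, class = c("uxp_coef_table", class(tab)),
            schedule = schedule, n_max = n_max)
}

UXP_SYMBOLIC_CAP <- 6L

# symbolic re-expansion of f^(k)(t0): every derivative of order n evaluated
# at a time other than tn is replaced by its Taylor series about tn,
# processed in increasing order and truncated above n_max; the surviving
# coefficient of f^(n)(tn) is the polynomial p_nk in t0..t_{n}.
reexpansion_polys <- function(n_max) {
  nvars <- n_max + 1L
  out <- vector("list", n_max)
  for (k in seq_len(n_max)) {
    # expand f^(k)(t0) about t_k for a (t0 - t_k) increment
    terms <- list() # key "n:i" -> poly coefficient of f^(n)(t_i)
    d0k <- poly_var_diff(0L, k, nvars)
    for (n in k:n_max) {
      coef <- poly_scale(poly_pow(d0k, n - k), q_new(1, factorial(n - k)))
      terms[[sprintf("%d:%d", n, k)]] <- coef
    }
    # walk orders upward, re-expanding stale evaluation points about tn
    for (n in k:n_max) {
      keys <- names(terms)
      for (key in keys) {
        parts <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
        if (parts[1] != n || parts[2] == n) next
        i <- parts[2]
        coef <- terms[[key]]
        terms[[key]] <- NULL
        din <- poly_var_diff(i, n, nvars)
        for (m in n:n_max) {
          add <- poly_mul(coef, poly_scale(poly_pow(din, m - n),
                                           q_new(1, factorial(m - n))))
          tgt <- sprintf("%d:%d", m, n)
          terms[[tgt]] <- if (is.null(terms[[tgt]])) add else poly_add(terms[[tgt]], add)
        }
      }
    }
    row <- vector("list", n_max)
    for (n in k:n_max) {
      p <- terms[[sprintf("%d:%d", n, n)]]
      row[[n]] <- if (is.null(p)) poly_zero(nvars) else p
    }
    out[[k]] <- row
  }
  out # out[[k]][[n]] = polynomial p_nk in variables t0..t_{n_max}
}

#' Coefficient table by symbolic re-expansion
#'
#' Mechanically repeats the derivation of the unsynchronized expansion:
#' each derivative `f^(n)` appearing at a time other than its own detection
#' time `tn` is replaced by its Taylor series about `tn`, in increasing
#' order of `n`, truncating above `n_max`, with all bookkeeping done in
#' exact polynomial algebra over the times. The surviving coefficient of
#' `f^(n)(tn)` inside the expansion of `f^(k)(t0)` is the polynomial
#' `p_nk`, returned here evaluated on `schedule`. The symbolic polynomials
#' are attached as the `"polys"` attribute.
#'
#' @inheritParams coefficient_table
#' @return A tibble with columns `n`, `k`, `p`, of class `uxp_coef_table`;
#'   attribute `"polys"` holds the exact polynomials (`polys[[k]][[n]]`).
#' @export
reexpansion_coefficient_table <- function(schedule, n_max) {
  stopifnot(inherits(schedule, "uxp_schedule"))
  n_max <- check_count(n_max, "n_max")
  if (n_max > UXP_SYMBOLIC_CAP) {
    abort_capability(sprintf(
      "symbolic re-expansion is supported up to order %d, got n_max = %d.",
      UXP_SYMBOLIC_CAP, n_max))
  }
  if (n_max > schedule$N) {
    abort_argument(sprintf("`n_max` = %d exceeds the schedule length N = %d.",
                           n_max, schedule$N))
  }
  polys <- reexpansion_polys(n_max)
  times <- c(schedule$t0, schedule$times)
  tab <- tidyr::expand_grid(n = seq_len(n_max), k = seq_len(n_max)) |>
    dplyr::filter(.data$k <= .data$n) |>
    dplyr::mutate(p = purrr::map2_dbl(.data$n, .data$k,
                                      ~ poly_eval(polys[[.y]][[.x]], times)))
  structure(tab, class = c("uxp_coef_table", class(tab)),
            schedule = schedule, n_max = n_max, polys = polys)
}
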