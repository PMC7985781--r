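# Coefficient algebra of the unsynchronized expansion.
#
# The coefficient p_nk multiplies f^(n)(tn) * tau^k / k! in the expansion of
# f(t0 + tau). Each p_nk is a sum over all strictly increasing index chains
# k = i0 < i1 < ... < ij < i_{j+1} = n with the intermediate indices drawn
# from {k+1, ..., n-1} (the empty chain included); a chain contributes the
# product over consecutive pairs of (t_{i_{m-1}} - t_{i_m})^(i_{m+1} - i_m) /
# (i_{m+1} - i_m)!, where the very first factor pairs t0 (not t_k) with the
# chain's first element. The chain count is 2^(n-k-1), so a hard cap on the
# order keeps the cost bounded.

UXP_ORDER_CAP <- 12L

# all subsets of the integers strictly between k and n, as a list of
# increasing integer vectors (the empty subset first)
index_chains <- function(k, n) {
  pool <- if (n - 1L >= k + 1L) seq.int(k + 1L, n - 1L) else integer(0)
  chains <- list(integer(0))
  for (i in pool) {
    chains <- c(chains, lapply(chains, function(s) c(s, i)))
  }
  chains
}

check_order_pair <- function(n, k, N = NULL) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (k > n) abort_argument(sprintf("need 1 <= k <= n, got k = %d > n = %d.", k, n))
  if (!is.null(N) && n > N) {
    abort_argument(sprintf("order n = %d exceeds the schedule length N = %d.", n, N))
  }
  if (n > UXP_ORDER_CAP) {
    abort_capability(sprintf(
      "order n = %d exceeds the supported cap of %d (chain count doubles per order).",
      n, UXP_ORDER_CAP))
  }
  invisible(list(n = n, k = k))
}

#' Expansion coefficient for an arbitrary detection schedule
#'
#' Computes the coefficient `p_nk` that multiplies `f^(n)(tn) * tau^k / k!`
#' in the unsynchronized expansion built on `schedule`. The identity cases
#' are `p_nn = 1` and `p_{k+1,k} = t0 - t_k`; for `n >= k + 2` the value is
#' the chain sum described in the package vignette, evaluated in double
#' precision.
#'
#' @param schedule a [detection_schedule()].
#' @param n derivative order (row), `1 <= n <= schedule$N`.
#' @param k power of the time increment (column), `1 <= k <= n`.
#' @return A single number.
#' @examples
#' s <- uniform_lag_schedule(t0 = 0, lag = 0.1, N = 4)
#' p_coefficient(s, 3, 1) # (3/2) * 0.1^2
#' @export
p_coefficient <- function(schedule, n, k) {
  stopifnot(inherits(schedule, "uxp_schedule"))
  ck <- check_order_pair(n, k, schedule$N)
  n <- ck$n
  k <- ck$k
  if (n == k) return(1)
  tt <- c(schedule$t0, schedule$times) # tt[i + 1] is the time of index i
  terms <- vapply(index_chains(k, n), function(chain) {
    idx <- c(k, chain, n)
    prod_ <- 1
    for (m in seq_len(length(idx) - 1L)) {
      left <- if (m == 1L) schedule$t0 else tt[idx[m - 1L] + 1L]
      a <- left - tt[idx[m] + 1L]
      e <- idx[m + 1L] - idx[m]
      prod_ <- prod_ * a^e / factorial(e)
    }
    prod_
  }, numeric(1))
  sum(terms)
}

# same chain sum with rational times (list of uxp_rational, index 0 = t0);
# used to establish the uniform-lag factorization in exact arithmetic
p_coefficient_exact <- function(times_q, n, k) {
  if (n == k) return(q_one())
  acc <- q_zero()
  for (chain in index_chains(k, n)) {
    idx <- c(k, chain, n)
    prod_ <- q_one()
    for (m in seq_len(length(idx) - 1L)) {
      left <- if (m == 1L) times_q[[1L]] else times_q[[idx[m - 1L] + 1L]]
      d <- q_add(left, q_neg(times_q[[idx[m] + 1L]]))
      e <- idx[m + 1L] - idx[m]
      f <- q_one()
      for (i in seq_len(e)) f <- q_mul(f, q_new(1, i)) # 1/e!
      pw <- q_one()
      for (i in seq_len(e)) pw <- q_mul(pw, d)
      prod_ <- q_mul(prod_, q_mul(pw, f))
    }
    acc <- q_add(acc, prod_)
  }
  acc
}

#' Exact rational coefficient for the uniform-lag schedule
#'
#' On the uniform-lag schedule `tn = t0 - n * t` the expansion coefficients
#' factor as `p_nk = c_nk * t^(n - k)` with `c_nk` a pure rational number:
#' 1 on the diagonal, `k` on the first subdiagonal, and for `k <= n - 2` a
#' chain sum over integer index differences. All arithmetic is exact.
#'
#' @param n derivative order, `n >= 1`.
#' @param k increment power, `1 <= k <= n`.
#' @return A [rational()] number.
#' @examples
#' c_coefficient(4, 1) # 8/3
#' as.numeric(c_coefficient(3, 2))
#' @export
c_coefficient <- function(n, k) {
  ck <- check_order_pair(n, k)
  n <- ck$n
  k <- ck$k
  if (n == k) return(q_one())
  acc <- q_zero()
  for (chain in index_chains(k, n)) {
    idx <- c(0L, k, chain, n) # index -1 of the chain convention maps to 0
    prod_ <- q_one()
    for (m in 2:(length(idx) - 1L)) {
      a <- idx[m] - idx[m - 1L]
      e <- idx[m + 1L] - idx[m]
      prod_ <- q_mul(prod_, q_pow_over_fact(a, e))
    }
    acc <- q_add(acc, prod_)
  }
  acc
}

#' Full coefficient table up to a truncation order
#'
#' Tabulates `p_nk` for all `1 <= k <= n <= n_max`. For a uniform-lag
#' schedule the exact rational factors `c_nk` and the lag power `n - k` are
#' included alongside the numeric value.
#'
#' @param schedule a [detection_schedule()].
#' @param n_max highest derivative order tabulated; capped (the chain count
#'   doubles with each order).
#' @return A tibble with columns `n`, `k`, `p` (and, for uniform-lag
#'   schedules, `c_num`, `c_den`, `c`, `t_power`), of class `uxp_coef_table`.
#' @examples
#' coefficient_table(uniform_lag_schedule(0, 0.1, 4), n_max = 4)
#' @export
coefficient_table <- function(schedule, n_max) {
  stopifnot(inherits(schedule, "uxp_schedule"))
  n_max <- check_count(n_max, "n_max")
  if (n_max > schedule$N) {
    abort_argument(sprintf("`n_max` = %d exceeds the schedule length N = %d.",
                           n_max, schedule$N))
  }
  if (n_max > UXP_ORDER_CAP) {
    abort_capability(sprintf("`n_max` = %d exceeds the supported cap of %d.",
                             n_max, UXP_ORDER_CAP))
  }
  grid <- tidyr::expand_grid(n = seq_len(n_max), k = seq_len(n_max)) |>
    dplyr::filter(.data$k <= .data$n)
  tab <- grid |>
    dplyr::mutate(p = purrr::map2_dbl(.data$n, .data$k,
                                      ~ p_coefficient(schedule, .x, .y)))
  if (inherits(schedule, "uxp_uniform_schedule")) {
    cs <- purrr::map2(tab$n, tab$k, c_coefficient)
    tab <- tab |>
      dplyr::mutate(
        c_num = purrr::map_dbl(cs, "num"),
        c_den = purrr::map_dbl(cs, "den"),
        c = .data$c_num / .data$c_den,
        t_power = .data$n - .data$k
      )
  }
  structure(tab, class = c("uxp_coef_table", class(tab)),
            schedule = schedule, n_max = n_max)
}

#' Write a coefficient table to CSV
#'
#' Numeric columns are written with 17 significant digits; for uniform-lag
#' tables the exact rationals appear as `"num/den"` strings in a `c_nk`
#' column.
#'
#' @param table a [coefficient_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coefficient_csv <- function(table, path) {
  stopifnot(inherits(table, "uxp_coef_table"))
  out <- tibble::tibble(n = table$n, k = table$k,
                        p_nk = sprintf("%.17g", table$p))
  if ("c_num" %in% names(table)) {
    out$c_nk <- ifelse(table$c_den == 1,
                       sprintf("%.0f", table$c_num),
                       sprintf("%.0f/%.0f", table$c_num, table$c_den))
    out$t_power <- table$t_power
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
print.uxp_coef_table <- function(x, ...) {
  cat("<coefficient table> n_max = ", attr(x, "n_max"), "\n", sep = "")
  NextMethod()
}
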