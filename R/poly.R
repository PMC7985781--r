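# Sparse multivariate polynomials over the detection times t0..tV with exact
# rational coefficients. Only what the symbolic re-expansion oracle needs:
# construction from time differences, addition, multiplication, powers,
# structural equality, and numeric evaluation. Monomials are keyed by their
# comma-joined exponent vector.

poly_zero <- function(nvars) {
  structure(list(terms = list(), nvars = nvars), class = "uxp_poly")
}

poly_key <- function(expv) paste(expv, collapse = ",")

poly_from_terms <- function(terms, nvars) {
  terms <- terms[vapply(terms, function(t) t$coef$num != 0, logical(1))]
  structure(list(terms = terms, nvars = nvars), class = "uxp_poly")
}

poly_const <- function(q, nvars) {
  if (q$num == 0) return(poly_zero(nvars))
  k <- poly_key(rep(0L, nvars))
  poly_from_terms(stats::setNames(list(list(expv = rep(0L, nvars), coef = q)), k), nvars)
}

# t_i - t_j (indices from 0; variable v maps to position v + 1)
poly_var_diff <- function(i, j, nvars) {
  if (i == j) return(poly_zero(nvars))
  e1 <- rep(0L, nvars); e1[i + 1L] <- 1L
  e2 <- rep(0L, nvars); e2[j + 1L] <- 1L
  terms <- stats::setNames(
    list(list(expv = e1, coef = q_one()), list(expv = e2, coef = q_new(-1, 1))),
    c(poly_key(e1), poly_key(e2)))
  poly_from_terms(terms, nvars)
}

poly_add <- function(a, b) {
  stopifnot(a$nvars == b$nvars)
  terms <- a$terms
  for (k in names(b$terms)) {
    if (is.null(terms[[k]])) {
      terms[[k]] <- b$terms[[k]]
    } else {
      terms[[k]]$coef <- q_add(terms[[k]]$coef, b$terms[[k]]$coef)
    }
  }
  poly_from_terms(terms, a$nvars)
}

poly_scale <- function(a, q) {
  terms <- lapply(a$terms, function(t) list(expv = t$expv, coef = q_mul(t$coef, q)))
  poly_from_terms(terms, a$nvars)
}

poly_mul <- function(a, b) {
  stopifnot(a$nvars == b$nvars)
  out <- list()
  for (ta in a$terms) {
    for (tb in b$terms) {
      expv <- ta$expv + tb$expv
      k <- poly_key(expv)
      coef <- q_mul(ta$coef, tb$coef)
      if (is.null(out[[k]])) {
        out[[k]] <- list(expv = expv, coef = coef)
      } else {
        out[[k]]$coef <- q_add(out[[k]]$coef, coef)
      }
    }
  }
  poly_from_terms(out, a$nvars)
}

poly_pow <- function(a, e) {
  out <- poly_const(q_one(), a$nvars)
  for (i in seq_len(e)) out <- poly_mul(out, a)
  out
}

poly_equal <- function(a, b) {
  if (a$nvars != b$nvars) return(FALSE)
  if (length(a$terms) != length(b$terms)) return(FALSE)
  ka <- sort(names(a$terms))
  if (!identical(ka, sort(names(b$terms)))) return(FALSE)
  all(vapply(ka, function(k) q_equal(a$terms[[k]]$coef, b$terms[[k]]$coef), logical(1)))
}

# times: numeric vector (t0, t1, ..., t_{nvars-1})
poly_eval <- function(a, times) {
  stopifnot(length(times) >= a$nvars)
  if (length(a$terms) == 0) return(0)
  sum(vapply(a$terms, function(t) {
    q_dbl(t$coef) * prod(times[seq_len(a$nvars)]^t$expv)
  }, numeric(1)))
}
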