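test_that("Taylor prediction sums the truncated series and honours tau = 0", {
  p <- taylor_predict(rep(1, 5), tau = 0.1, nt = 4)
  expect_equal(p$value, 1 + 0.1 + 0.1^2 / 2 + 0.1^3 / 6 + 0.1^4 / 24)
  expect_identical(p$scheme, "Taylor")
  expect_identical(taylor_predict(c(2.5, 1, 1), tau = 0)$value, 2.5)
  expect_error(taylor_predict(c(1, 1), tau = 0.1, nt = 2), class = "uxp_argument_error")
})

test_that("Taylor prediction of sine agrees with independent term-by-term summation", {
  t0 <- pi / 4
  tau <- 0.2
  derivs <- vapply(0:3, function(k) sin_traj$deriv(t0, k), numeric(1))
  got <- taylor_predict(derivs, tau, 3)$value
  # the alternating sin/cos pattern, written out literally
  ref <- sin(t0) + cos(t0) * tau - sin(t0) * tau^2 / 2 - cos(t0) * tau^3 / 6
  expect_equal(got, ref, tolerance = 1e-15)
})

test_that("a degenerate schedule makes the unsynchronized prediction identical to Taylor", {
  t0 <- 0.3
  derivs <- vapply(0:6, function(k) exp_traj$deriv(t0, k), numeric(1))
  obs <- derivative_observations(
    tibble::tibble(n = 1:6, t = t0, value = derivs[-1]), t0 = t0, f0 = derivs[1])
  for (nt in 1:6) {
    for (tau in c(0.01, 0.3, 1.5)) {
      expect_identical(u_predict(obs, tau, nt)$value,
                       taylor_predict(derivs, tau, nt)$value)
    }
  }
})

test_that("the expansion is exact on polynomials whatever the schedule", {
  set.seed(404)
  fn <- test_function("polynomial", coeffs = c(2, -1, 3)) # 3x^2 - x + 2
  for (rep in 1:50) {
    s <- random_schedule(4)
    tau <- stats::runif(1, 0, 2)
    obs <- uxpand:::exact_observations(fn, s)
    got <- u_predict(obs, tau, 2)$value
    x <- s$t0 + tau
    expect_equal(got, 3 * x^2 - x + 2, tolerance = 1e-12)
  }
})

test_that("generic prediction reproduces the printed exponential expansion", {
  obs <- uniform_exact_obs(exp_traj, t0 = 0, lag = 0.05, N = 3)
  got <- u_predict(obs, tau = 0.5, nt = 3)$value
  expect_equal(got, eq_exp_uniform(0, 0.05, 0.5, 3), tolerance = 1e-14)
})

test_that("uniform-lag prediction reproduces the printed sine expansion", {
  obs <- uniform_exact_obs(sin_traj, t0 = pi / 4, lag = 0.1, N = 4)
  got <- u_predict_uniform(obs, tau = 0.3, nt = 4)$value
  expect_equal(got, eq_sin_uniform(pi / 4, 0.1, 0.3, 4), tolerance = 1e-14)
})

test_that("uniform-lag and generic evaluators agree on random draws", {
  set.seed(505)
  worst <- 0
  for (rep in 1:100) {
    lag <- stats::runif(1, 1e-3, 0.2)
    tau <- stats::runif(1, 0.01, 1)
    nt <- sample(1:5, 1)
    obs <- uniform_exact_obs(exp_traj, t0 = 0, lag = lag, N = nt)
    a <- u_predict(obs, tau, nt)$value
    b <- u_predict_uniform(obs, tau, nt, lag = lag)$value
    worst <- max(worst, abs(a - b) / abs(b))
  }
  expect_lt(worst, 1e-13)
})

test_that("the uniform-lag prediction is continuous in the lag at zero", {
  nt <- 4
  obs <- uniform_exact_obs(exp_traj, t0 = 0, lag = 1e-9, N = nt)
  u <- u_predict_uniform(obs, tau = 0.5, nt = nt)$value
  ty <- taylor_predict(rep(1, nt + 1), tau = 0.5, nt = nt)$value
  expect_lt(abs(u - ty) / abs(ty), 1e-7)
})

test_that("each extra retained order buys about one extra power of tau", {
  taus <- exp(seq(log(1e-3), log(1e-2), length.out = 12))
  slopes <- vapply(1:3, function(nt) {
    errs <- vapply(taus, function(tau)
      abs(truncation_error(exp_traj, 0, 1e-6, tau, nt, "U")), numeric(1))
    unname(stats::coef(stats::lm(log(errs) ~ log(taus)))[2])
  }, numeric(1))
  expect_equal(diff(slopes), c(1, 1), tolerance = 0.2)
})

test_that("observations round-trip through CSV with the n = 0 base row", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    n = 0:2, t = c(0.1, 0.05, 0.02), value = c(2, 0.5, -1)), path)
  obs <- read_observations(path)
  expect_equal(obs$t0, 0.1)
  expect_equal(obs$f0, 2)
  expect_equal(obs$data$value, c(0.5, -1))
  # missing base row is rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(n = 1:2, t = c(0.05, 0.02), value = c(0.5, -1)), bad)
  expect_error(read_observations(bad), class = "uxp_argument_error")
})

test_that("observation sets validate contiguity and the uniform evaluator its pattern", {
  expect_error(
    derivative_observations(tibble::tibble(n = c(1, 3), t = 0, value = 1), 0, 1),
    class = "uxp_argument_error")
  expect_error(
    derivative_observations(tibble::tibble(n = c(1, 1), t = 0, value = 1), 0, 1),
    class = "uxp_argument_error")
  obs <- derivative_observations(
    tibble::tibble(n = 1:2, t = c(-0.01, -0.0205), value = 1), t0 = 0, f0 = 1)
  expect_error(u_predict_uniform(obs, 0.1, 2, lag = 0.01), class = "uxp_argument_error")
  expect_error(u_predict(obs, 0.1, 3), class = "uxp_argument_error")
})
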