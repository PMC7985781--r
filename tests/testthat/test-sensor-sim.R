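test_that("noise-free streams store exact derivatives at the stated times", {
  st <- generate_stream(exp_traj, stream_schedule("uniform", lag = 0.01, N = 4),
                        t0 = 0, sigma = 0, seed = 1)
  obs <- st[st$n > 0, ]
  expect_equal(obs$time, -(1:4) * 0.01)
  expect_equal(obs$value, exp(-(1:4) * 0.01), tolerance = 1e-12)
  expect_equal(st$value[st$n == 0], 1)
})

test_that("streams are reproducible from their seed and the RNG state is restored", {
  sched <- stream_schedule("jittered", lag = 0.01, N = 3, jitter = 0.004)
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  a <- generate_stream(sin_traj, sched, t0 = seq(0, 1, 0.1), sigma = 1e-4, seed = 42)
  after <- stats::runif(1)
  b <- generate_stream(sin_traj, sched, t0 = seq(0, 1, 0.1), sigma = 1e-4, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(before, after) # caller's RNG stream untouched
})

test_that("jittered schedules respect the max-gap budget", {
  lag <- 0.008
  jit <- 0.002
  st <- generate_stream(exp_traj, stream_schedule("jittered", lag = lag, N = 5, jitter = jit),
                        t0 = seq(0, 1, 0.05), seed = 5)
  for (s in unique(st$step)) {
    rows <- st[st$step == s, ]
    sched <- detection_schedule(rows$t0[1], rows$time[rows$n > 0])
    expect_lte(max_gap(sched), lag + jit)
  }
})

test_that("noise-free uniform streams predict better than the next-lower Taylor truncation", {
  st <- generate_stream(exp_traj, stream_schedule("uniform", lag = 0.01, N = 4),
                        t0 = 0, sigma = 0, seed = 1)
  obs <- uxpand:::stream_observations(st, 1)
  err <- abs(exp(0.5) - u_predict(obs, 0.5, 4)$value)
  expect_lt(err, abs(truncation_error(exp_traj, 0, 0, 0.5, 3, "Taylor")))
})

test_that("rolling prediction is exact on polynomial trajectories", {
  fn <- test_function("polynomial", coeffs = c(1, -2, 0.5))
  st <- generate_stream(fn, stream_schedule("uniform", lag = 0.02, N = 2),
                        t0 = seq(0, 2, 0.1), sigma = 0, seed = 8)
  res <- rolling_prediction(st, tau = 0.7, nt = 2)
  expect_lt(res$max_abs_error, 1e-10)
  expect_equal(glance(res)$rms_error, sqrt(mean(tidy(res)$error^2)))
})

test_that("rolling sine predictions beat the next-lower Taylor truncation", {
  st <- generate_stream(sin_traj, stream_schedule("uniform", lag = 0.01, N = 3),
                        t0 = seq(pi / 4, pi / 4 + 1, 0.05), sigma = 0, seed = 2)
  res <- rolling_prediction(st, tau = 0.3, nt = 3)
  expect_lt(res$max_abs_error,
            abs(truncation_error(sin_traj, pi / 4, 0, 0.3, 2, "Taylor")))
})

test_that("prediction error grows with observation noise and stays in the expected band", {
  sched <- stream_schedule("uniform", lag = 0.01, N = 4)
  t0s <- seq(0, by = 0.005, length.out = 200)
  rms <- vapply(c(0, 1e-5, 1e-4, 1e-3), function(sg) {
    st <- generate_stream(exp_traj, sched, t0 = t0s, sigma = sg, seed = 7)
    glance(rolling_prediction(st, 0.1, 4))$rms_error
  }, numeric(1))
  expect_false(is.unsorted(rms))

  st0 <- generate_stream(exp_traj, sched, t0 = seq(0, by = 0.001, length.out = 1000),
                         sigma = 0, seed = 11)
  st1 <- generate_stream(exp_traj, sched, t0 = seq(0, by = 0.001, length.out = 1000),
                         sigma = 1e-4, seed = 11)
  r0 <- glance(rolling_prediction(st0, 0.1, 4))$rms_error
  r1 <- glance(rolling_prediction(st1, 0.1, 4))$rms_error
  expect_gt(r1, r0)
  expect_gt(r1, 1e-5)
  expect_lt(r1, 1e-2)
})

test_that("arbitrary jittered schedules keep the uniform-case short-horizon accuracy", {
  # max_gap <= 0.01 as in the uniform lag-0.01 case; horizons up to the gap
  st <- generate_stream(exp_traj,
                        stream_schedule("jittered", lag = 0.008, N = 2, jitter = 0.002),
                        t0 = seq(0, 0.5, 0.01), sigma = 0, seed = 3)
  worst <- max(vapply(seq(0.001, 0.01, length.out = 8), function(tau)
    glance(rolling_prediction(st, tau, 2))$max_abs_error, numeric(1)))
  expect_lt(worst, 1e-5)
})

test_that("streams and experiments serialize to JSON-lines, CSV and a summary", {
  st <- generate_stream(exp_traj, stream_schedule("uniform", lag = 0.01, N = 2),
                        t0 = c(0, 0.1), sigma = 0, seed = 1)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_stream_jsonl(st, jl)
  lines <- readLines(jl)
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$t0, 0.1)
  expect_equal(nrow(rec$observations), 2)

  res <- rolling_prediction(st, 0.05, 2)
  csvp <- withr::local_tempfile(fileext = ".csv")
  smp <- withr::local_tempfile(fileext = ".json")
  write_experiment_csv(res, csvp, smp)
  got <- readr::read_csv(csvp, show_col_types = FALSE)
  expect_equal(nrow(got), 2)
  summ <- jsonlite::read_json(smp)
  expect_equal(summ$rms_error, glance(res)$rms_error, tolerance = 1e-12)
})

test_that("stream and experiment arguments are validated", {
  st <- generate_stream(exp_traj, stream_schedule("uniform", lag = 0.01, N = 2),
                        t0 = 0, seed = 1)
  expect_error(rolling_prediction(st, 0.1, 3), class = "uxp_argument_error")
  expect_error(generate_stream(exp_traj, stream_schedule("uniform", lag = 0.01, N = 2),
                               t0 = 0, sigma = -1), class = "uxp_argument_error")
  expect_error(stream_schedule("explicit"), class = "uxp_argument_error")
  expect_error(test_function("polynomial"), class = "uxp_argument_error")
})
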