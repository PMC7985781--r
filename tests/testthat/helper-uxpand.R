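# shared fixtures: random schedules and independent evaluators of the
# printed uniform-lag expansions, used as oracles against the generic code

random_schedule <- function(N, t0 = NULL) {
  if (is.null(t0)) t0 <- stats::runif(1, -0.5, 0.5)
  detection_schedule(t0, t0 - stats::runif(N, 0, 0.3))
}

exp_traj <- test_function("exp")
sin_traj <- test_function("sin")

# direct evaluation of the exponential uniform-lag expansion, bracket by
# bracket with the literal printed coefficients, truncated at order nt <= 4
eq_exp_uniform <- function(t0, lag, tau, nt) {
  stopifnot(nt <= 4)
  brackets <- list(
    tau,
    tau^2 / 2 + lag * tau,
    tau^3 / 6 + 2 * lag * tau^2 / 2 + (3 / 2) * lag^2 * tau,
    tau^4 / 24 + 3 * lag * tau^3 / 6 + 4 * lag^2 * tau^2 / 2 + (8 / 3) * lag^3 * tau)
  v <- exp(t0)
  for (n in seq_len(nt)) v <- v + exp(t0 - n * lag) * brackets[[n]]
  v
}

# same for the sine expansion (phase-shifted derivative signs)
eq_sin_uniform <- function(t0, lag, tau, nt) {
  stopifnot(nt <= 4)
  brackets <- list(
    tau,
    tau^2 / 2 + lag * tau,
    tau^3 / 6 + 2 * lag * tau^2 / 2 + (3 / 2) * lag^2 * tau,
    tau^4 / 24 + 3 * lag * tau^3 / 6 + 4 * lag^2 * tau^2 / 2 + (8 / 3) * lag^3 * tau)
  signs <- c(1, -1, -1, 1) # cos, -sin, -cos, +sin evaluated via phase shift
  fns <- list(cos, sin, cos, sin)
  v <- sin(t0)
  for (n in seq_len(nt)) {
    v <- v + signs[n] * fns[[n]](t0 - n * lag) * brackets[[n]]
  }
  v
}

uniform_exact_obs <- function(fn, t0, lag, N) {
  uxpand:::exact_observations(fn, uniform_lag_schedule(t0, lag, N))
}
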