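---
title: "Predicting ahead from unsynchronized derivative observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ahead from unsynchronized derivative observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uxpand)
```

## The problem

Sensorimotor control has to predict where a physiological signal is heading
within a few milliseconds of a stimulus. The information available for that
prediction is peculiar: different receptor populations report the value of
the signal *and its time derivatives* (slow-adapting receptors the level,
fast-adapting receptors the rates of change), and each piece arrives tagged
with its own detection time. Nothing is synchronized. A Taylor polynomial
about a single time `t0` cannot consume such data directly — it needs every
derivative evaluated at the same instant.

`uxpand` implements a power-series predictor built exactly for this
situation. Given the signal value `f(t0)` and one observation of each
derivative order, `f^(n)(t_n)` at its own detection time `t_n`, the
truncated unsynchronized expansion estimates

```
f(t0 + tau)  ~  f(t0) + sum_{n=1}^{nt} f^(n)(t_n) * sum_{k=1}^{n} tau^k/k! * p_nk
```

where the coefficients `p_nk` depend only on the detection schedule
`(t0, t1, ..., tN)`. When every `t_n` equals `t0` the inner sums collapse
and the expression is the Taylor polynomial: the scheme is a strict
generalization. All times are dimensionless, normalized to an arbitrary
time constant, so a lag of 0.01 means "one hundredth of the signal's
characteristic time", not a number of seconds.

## The coefficient algebra

`p_nn = 1` and `p_{k+1,k} = t0 - t_k` always. For `n >= k + 2` the
coefficient is a sum over all strictly increasing integer chains
`k = i_0 < i_1 < ... < i_j < i_{j+1} = n` whose intermediate entries come
from `{k+1, ..., n-1}` (the empty chain included). A chain contributes the
product over consecutive pairs of

```
(t_{i_{m-1}} - t_{i_m})^(i_{m+1} - i_m) / (i_{m+1} - i_m)!
```

with the first factor pairing `t0` with the chain's first element. Each
chain records one route by which a stale derivative evaluation was pushed
forward through nested Taylor re-expansions, which is where the structure
comes from. There are `2^(n-k-1)` chains, so the cost doubles per order;
`coefficient_table()` enforces a hard cap at order 12 and raises a
capability error beyond it, because a predictor that silently takes
exponentially long is worse than one that refuses.

On the *uniform-lag* schedule `t_n = t0 - n*t` — the worst regular case,
every derivative as stale as its order allows — the time differences
become integer multiples of the lag and the coefficients factor as
`p_nk = c_nk * t^(n-k)` with `c_nk` a pure rational: 1 on the diagonal,
`k` on the first subdiagonal, `3/2, 2` and `8/3, 4, 3` in the next two
rows. `c_coefficient()` computes these in exact integer-pair rational
arithmetic (gcd-reduced, overflow-guarded below 2^53): the published
values are exact fractions and comparing them through floating point
would blur the one place where exactness is cheap. No installed package
provides exact rationals, so the package carries its own minimal type.

### Two independent oracles

The chain sum is easy to get subtly wrong, so the package ships two
derivations that share no code with it and are tested against it
(`n <= 6`, relative tolerance 1e-10, random schedules):

* `monomial_coefficient_table()` imposes exactness on the monomials
  `(t - t0)^m`: matching powers of `tau` gives a triangular system whose
  forward solution determines every `p_mk` from lower rows.
* `reexpansion_coefficient_table()` replays the nested re-expansion
  derivation mechanically — every derivative evaluated away from its own
  detection time is replaced by its Taylor series about that time, in
  increasing order, truncated at `n_max` — using sparse multivariate
  polynomials over the times with rational coefficients. Its low-order
  output is also compared term by term against hand-built reference
  polynomials such as `p_31 = (t0-t1)^2/2! + (t0-t1)(t1-t2)`. The
  symbolic route is capped at order 6; beyond that the polynomials grow
  without telling us anything new.

## Truncation error against the Taylor series

`truncation_error()` and `error_curve()` score both schemes on analytic
test functions (`exp` about `t0 = 0`, `sin` about `t0 = pi/4`,
polynomials) with derivative values taken exactly, so the only error is
truncation plus staleness. The error is stored *signed* — exact value
minus truncated series — because the sign carries information; magnitude
comparisons take `abs()` and the bundled `autoplot()` uses log-log axes.
The behaviour, reproduced by the test suite, has three regimes:

* **Lag far below the horizon** (`t <= 0.001`, `tau >= 0.1`): the curve is
  close to the Taylor curve of the same order. The relative gap scales
  like `nt*(nt+1)*t/tau`, so it is a few percent for `nt = 2` but grows
  to ~20% for `nt = 4` at `tau = 0.1` — visually coincident on a log
  plot, not numerically coincident. Tests that assert this regime use the
  measured scaling, not wishful tightness.
* **Moderate lag** (`t` of 0.01–0.05, `tau >= 0.2`): the error stays below
  the Taylor series truncated one order lower, with one marginal
  exception at the very edge (`sin`, `t = 0.05`, `nt = 4`, `tau = 0.2`,
  ratio ≈ 1.1) where the claim is only approximately true.
* **Horizon near or below the lag**: the curve drifts up towards
  lower-order Taylor curves, crossing them; for `exp`, the order-3 curve
  at `t = 0.05` crosses the order-2 Taylor curve near `tau ≈ 0.064`. For
  `t <= 0.01` and `0 < tau <= t` the error is negligible anyway: about
  1e-5, 1e-7 and 1e-9 for `nt = 2, 3, 4` — "about" is held in the tests
  as a strict bound at twice those magnitudes with a logged note in
  between, since the magnitudes themselves are order-of-magnitude
  statements (the exp case at `nt = 4` measures 1.05e-9).

Default grids mirror the two useful regimes: `tau_grid_log(1e-3, 1, 60)`
for the overview and `tau_grid_linear()` (200 points) for short-range
detail. Grid densities are a reporting choice, not part of the model.

## The sampled-signal baseline

If only the signal itself is recorded, at period `T`, derivatives must be
estimated. `backward_fd_derivative()` builds the n-th-order-accurate
backward finite-difference estimate from the `2n` most recent samples,
solving the Vandermonde moment conditions at run time rather than
hard-coding stencil tables (the conditions, not the tables, are the
definition). `backward_fd_predict()` then runs the Taylor polynomial on
those estimates and reports the cost that motivates the whole package:
the estimate needs samples reaching back `(2n-1)*T`, an acquisition lag a
directly sensed derivative does not pay, and at equal truncation order
its prediction error is larger (the suite checks both).

## The synthetic sensor stream

`generate_stream()` is the package's stand-in for receptor data: a known
trajectory observed on a rolling span of base times, each derivative
order at a scheduled offset — uniform (`t0 - n*lag`), jittered (uniform
perturbation of total width `jitter`, so successive gaps never exceed
`lag + jitter`), or explicit offsets — with optional additive i.i.d.
Gaussian noise of standard deviation `sigma` on every observed value.
Defaults emulate the regime the error analysis identifies as
biologically interesting: lags around 0.01 of the signal's time constant
(fast receptor discharge) and horizons an order of magnitude longer.
Noise is the minimal stand-in for receptor variability; `sigma = 0`
recovers the noiseless setting exactly, and the generator is
bit-reproducible from its seed with the caller's RNG state restored.

What the generator deliberately does **not** emulate: spike-train
encoding, receptor adaptation, conduction delays, or any closed feedback
loop. A passing experiment therefore shows that the *prediction* stage
behaves as derived, not that a physiological controller built on it
would.

`rolling_prediction()` scores the expansion at every base time against
the true trajectory; `tidy()` returns the per-step records, `glance()`
the max-absolute and RMS errors. Monte-Carlo checks in the suite use 200
steps for the noise-monotonicity property and 1000 steps for the RMS
band of the `sigma = 1e-4` condition — sizes chosen to make the
statistics stable at desk scale.

## Numerical choices

* Series evaluation shares one iteratively built `tau^k/k!` vector across
  every scheme, and accumulates order contributions in increasing `n`.
  With a degenerate schedule the unsynchronized path then reproduces the
  Taylor value *bitwise*, which the tests assert with `expect_identical()`.
* Repeated or unordered detection times are allowed: the chain factors
  vanish gracefully and nothing in the derivation needs distinctness.
* `u_predict_uniform()` verifies the uniform pattern to an absolute
  1e-12 before trusting the rational fast path.
* No convergence-radius checking is attempted; truncation error is the
  caller's concern and `error_curve()` is the tool for it.
* The order-consistency property (each retained order buys one power of
  `tau`) is checked by log-log slope fitting for `nt = 1..3` on
  `tau` in `[1e-3, 1e-2]`; at `nt = 4` the residual there falls to ~1e-17,
  below double-precision resolution of values of order 1, so a fitted
  slope would measure rounding noise rather than order.

## Limitations

Scalar signals only — no vector states, no multivariate time. Exact
derivative *values* are assumed available from the sensors; the package
estimates derivatives only inside the finite-difference baseline. The
rational type overflows (loudly) past 2^53, which in practice bounds
exact tables around order 12; and the symbolic oracle is a validation
tool, not a fast path.
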