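# uxpand

Prediction of a smooth signal's forward evolution from its value and the
values of its time derivatives observed at **arbitrarily different
(unsynchronized) times** — the situation faced by the sensorimotor system,
where different receptor populations report a physiological parameter and
its rates of change with different latencies, and by any controller fed by
staggered sensors.

The Taylor polynomial needs every derivative at one instant `t0`. `uxpand`
implements the unsynchronized expansion that does not: given `f(t0)` and
one observation `f⁽ⁿ⁾(tₙ)` per derivative order, each at its own detection
time, the truncated prediction is

    f(t0 + τ) ≈ f(t0) + Σₙ f⁽ⁿ⁾(tₙ) · Σₖ τᵏ/k! · pₙₖ      (n = 1..nt, k = 1..n)

with coefficients `pₙₖ` determined by the detection schedule alone:
`pₙₙ = 1`, `p_{k+1,k} = t0 − tₖ`, and for lower columns a sum over
increasing index chains of products `(t_{i} − t_{j})^e / e!`. When all
`tₙ = t0` the scheme **is** the Taylor series. On the uniform-lag schedule
`tₙ = t0 − n·t` the coefficients factor as `pₙₖ = cₙₖ·t^(n−k)` with exact
rational `cₙₖ` (1; 1, 1; 3/2, 2, 1; 8/3, 4, 3, 1; ...), which the package
computes in exact rational arithmetic.

The package is tidyverse-shaped: predictions, coefficient tables, error
curves and experiment records are tibbles; result objects have `tidy()`,
`glance()` and `autoplot()` methods.

What's inside:

* `detection_schedule()`, `uniform_lag_schedule()`, `max_gap()` — schedules
  and the lag statistic that controls accuracy.
* `p_coefficient()`, `c_coefficient()`, `coefficient_table()` — the
  coefficient algebra, plus two independent derivations
  (`monomial_coefficient_table()`, `reexpansion_coefficient_table()`) used
  as cross-checks.
* `taylor_predict()`, `u_predict()`, `u_predict_uniform()` — the predictors.
* `truncation_error()`, `error_curve()`, `max_abs_error()` — truncation
  error versus the Taylor series on analytic test functions.
* `sampled_record()`, `backward_fd_derivative()`, `backward_fd_predict()` —
  the backward finite-difference baseline that pays an acquisition lag of
  `(2n−1)·T` for an order-n derivative estimate.
* `generate_stream()`, `rolling_prediction()` — a seeded generator of
  synthetic, optionally noisy, staggered sensor observations and rolling
  prediction experiments on it.
* `uxp_cli()` — subcommands `coeffs`, `predict`, `error-curves`,
  `simulate` (thin wrapper script in `inst/cli/uxpand`).

## Worked example

Predict `exp` a quarter time-constant ahead from derivatives observed
10, 20 and 30 thousandths *earlier* than the base time:

```r
library(uxpand)

obs <- derivative_observations(
  data.frame(n = 1:3,
             t = c(-0.01, -0.02, -0.03),
             value = exp(c(-0.01, -0.02, -0.03))),
  t0 = 0, f0 = 1)

u_predict(obs, tau = 0.25, nt = 3)
#> # A tibble: 1 × 4
#>   scheme    nt   tau value
#>   <chr>  <int> <dbl> <dbl>
#> 1 U          3  0.25  1.28
```

The predicted value is 1.2837642857 against the true `exp(0.25)` =
1.2840254167: an error of 2.6e-4, essentially the 1.7e-4 truncation error
a third-order Taylor polynomial would make *with synchronized data*
(1.2838541667), even though no two observations here share a time stamp.

The uniform-lag coefficient table shows the exact rational structure:

```r
coefficient_table(uniform_lag_schedule(0, 0.01, 4), 4)
#> <coefficient table> n_max = 4
#> # A tibble: 10 × 7
#>        n     k          p c_num c_den     c t_power
#>    <int> <int>      <dbl> <dbl> <dbl> <dbl>   <int>
#>  1     1     1 1              1     1  1          0
#>  2     2     1 0.01           1     1  1          1
#>  3     2     2 1              1     1  1          0
#>  4     3     1 0.00015        3     2  1.5        2
#>  5     3     2 0.02           2     1  2          1
#>  ...
```

Short-horizon accuracy at lag 0.01 (third-order truncation, horizons up to
the lag):

```r
curve <- error_curve(test_function("exp"), 0, lag = 0.01, nt = 3,
                     tau_grid = tau_grid_linear(1e-4, 0.01, 100))
max_abs_error(dplyr::filter(curve, scheme == "U"), c(0, 0.01))
#> [1] 5.109092e-08
```

A noisy rolling experiment over a sine trajectory:

```r
st <- generate_stream(test_function("sin"),
                      stream_schedule("uniform", lag = 0.01, N = 3),
                      t0 = seq(0, 2, by = 0.05), sigma = 1e-4, seed = 7)
glance(rolling_prediction(st, tau = 0.2, nt = 3))
#> # A tibble: 1 × 5
#>   steps    nt   tau max_abs_error rms_error
#>   <int> <int> <dbl>         <dbl>     <dbl>
#> 1    41     3   0.2      0.000276  0.000139
```

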