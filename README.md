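# hawksvr

Hybrid metaheuristic forecasting of daily fine particulate matter
(PM2.5) concentrations. The package couples a from-scratch **Harris
Hawks Optimization** (HHO) to an **ε-insensitive support vector
regression** (SVR) with Gaussian RBF kernel: HHO searches the
hyperparameter box $(C, \sigma) \in [1, 1000]^2$ to minimise a 10-fold
cross-validated mean absolute percentage error (MAPE), and the
surrounding evaluation protocol — repeated independent runs,
best/worst/average/SD summaries, and the Friedman rank test for
comparing optimizers — is included, together with a reader for the
CDC/EPA Downscaler daily county-level PM2.5 CSV schema and
seed-deterministic synthetic-data generators.

## The method in brief

* **HHO** (`hho_optimize()`): a population of $N$ hawks chases the
  best-so-far "rabbit". Each hawk, each iteration, draws an initial
  energy $E_0 \in (-1,1)$; the decayed escape energy
  $E = 2E_0(1 - t/T)$ selects global exploration ($|E| \ge 1$) or one
  of four besiege strategies (soft/hard, with or without greedy
  Lévy-flight dives) split at $|E| = 0.5$ and an escape draw
  $r = 0.5$. Candidates are clipped to the bounds before evaluation;
  the convergence curve is monotone by construction.
* **SVR** (`svr_fit()`): solves the dual
  $\min_\beta \tfrac12 \beta^\top K \beta + \varepsilon\|\beta\|_1 -
  y^\top \beta$ s.t. $\sum\beta_i = 0$, $|\beta_i| \le C$ with a
  compiled sequential-minimal-optimization solver (second-order
  working-set selection); the reported KKT residual of a fitted model
  is below $10^{-6}$, verified in the tests against an independent
  interior-point QP oracle.
* **Tuning** (`tune_svr()`, `run_experiment()`): the objective
  (`cv_mape_objective()`) fits the SVR on $k-1$ folds, predicts the
  held fold, maps back to concentration units, and averages the fold
  MAPEs; experiments repeat the trial with seeds derived from a master
  seed and aggregate per-run best MAPEs.
* **Ranking** (`friedman_test()`): average within-run ranks,
  chi-square with the classical tie correction, upper-tail p-value at
  $k-1$ degrees of freedom.

## Worked example

Rank the eight published metaheuristic-tuned SVR hybrids from the
packaged ten-run MAPE matrix of county 1001:

```r
library(hawksvr)

m  <- mape_run_table(1001)
fr <- friedman_test(as.matrix(m[-1]))
fr
#> <Friedman rank test: 10 blocks x 8 algorithms>
#>   chi-square = 68.7000 (df = 7), p = 2.704e-12, tie-corrected
#>   EO  GWO HGSO  BMO MRFO  SSA  WOA  HHO
#>  7.0  1.6  5.0  2.9  4.0  6.0  8.0  1.5
```

The HHO-tuned SVR has the best (lowest) mean rank, 1.5, and the
differences across algorithms are overwhelmingly significant
(p ≈ 2.7e-12). Tune a forecaster on a synthetic PM2.5-like series:

```r
series <- gen_pm25_series(series_spec(n = 400, seed = 1))
cfg <- tuning_config(n_agents = 10, max_iter = 10, runs = 3)
report <- pm25_tune(
  tibble::tibble(date = series$date, value = series$pm25),
  cfg, n_lags = 7, holdout_frac = 0.2, master_seed = 1)
report
#> <SVR tuning report>
#>   runs: 3 | best 0.323538 | worst 0.32725 | average 0.325556 | sd 0.00188
#>   best (C, sigma) = (31.71, 4.003) | cpu 13.3s
#>   holdout MAPE: 0.255071
```

The per-run best cross-validated MAPEs are tightly clustered (SD 0.002
across three runs), and the final model's holdout MAPE (25.5%) is in
line with the cross-validated estimate. The large absolute error is a
property of this short, deliberately noisy synthetic series — its
day-to-day variation is mostly irreducible — not of the tuner; on the
low-noise regression testbed (`gen_svr_recoverable()`) the same
pipeline reaches within ~1.1x of the generator's noise floor.
`tidy(report)` returns the per-run table, `glance(report)` the one-row
summary in the conventional Best/Worst/Average/SD/CPU/C/Alpha layout,
and `autoplot(report)` the per-run convergence curves.

A thin command-line front end ships in `inst/exec/hawksvr`
(`tune`, `compare`, `simulate` subcommands).

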