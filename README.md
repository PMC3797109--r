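# carrygoose

Carry-over effects in migratory capital breeders: do light-bellied Brent
geese (*Branta bernicla hrota*) that leave spring staging heavier rear more
offspring — and does the answer depend on the weather they meet on the
Arctic breeding grounds?

`carrygoose` is an R implementation of that individual-level analysis for
ecologists working on seasonal interactions. Each female contributes one
spring capture (mass, skull length, day of the annual cycle) and one
response: the number of juveniles she returns to the wintering grounds with
the following year. The package covers the whole workflow:

* **Covariate construction** — scaled mass index
  `SMI = M (L0/L)^b_SMA` with the SMA exponent estimated as OLS slope /
  correlation of log mass on log skull; seasonal correction by a quadratic
  day-of-cycle polynomial; quadratic detrending of the June NAO series;
  conservative breeder/non-breeder assignment from winter resightings;
  z-standardisation with standardize-then-square interaction columns.
* **A Poisson random-intercept GLMM engine** — log link, year intercept,
  maximum likelihood by Laplace approximation with analytic gradients,
  validated against `stats::glm` (σ = 0), an independent 64-node adaptive
  Gauss–Hermite oracle, and `lme4`.
* **Information-theoretic selection** — AICc
  (`-2ℓ + 2k + 2k(k+1)/(n-k-1)`), Akaike weights, the Δ6 set, the nesting
  rule, and model averaging (natural and shrinkage estimators,
  unconditional SEs, relative importance), plus marginal R² for the
  Poisson GLMM.
* **Bayesian layers** — an MCMC refit of the top model for predicted means
  with 95% credible intervals across good/poor NAO scenarios, and a
  bivariate mass/offspring latent-variable model whose residual correlation
  `r = C / sqrt(V_mass · V_juv)` is the carry-over statistic.
* **A synthetic-data generator** — the original field data are not
  deposited, so the generator reproduces the assumed generative structure
  (213 females over 6 years by default) and every estimator is validated by
  parameter recovery against known truth.

## Worked example

The selection arithmetic, run on the published candidate-set summaries that
ship with the package (`reference_model_set()`):

```r
library(carrygoose)

ref <- reference_model_set()
tab <- apply_nesting_rule(rank_models(ref[, c("name", "k", "loglik")], n = 213))
tab
#>           name k   loglik  aicc delta weight in_delta_set retained
#> 1 Mass^2 * NAO 6 -169.018 350.4  0.00  0.507         TRUE     TRUE
#> 2   Mass * NAO 5 -170.293 350.9  0.43  0.408         TRUE     TRUE
#> 3          NAO 3 -174.799 355.7  5.27  0.036         TRUE     TRUE
#> 4   Mass + NAO 4 -173.832 355.9  5.41  0.034         TRUE    FALSE
#> 5 Mass^2 + NAO 5 -173.625 357.5  7.10  0.015        FALSE    FALSE
#> 6         Null 2 -182.591 369.2 18.80  0.000        FALSE    FALSE
#> 7         Mass 3 -181.778 369.7 19.23  0.000        FALSE    FALSE
#> 8       Mass^2 4 -181.503 371.2 20.75  0.000        FALSE    FALSE
```

Four models sit within Δ6 of the best; the nesting rule drops `Mass + NAO`
because the simpler `NAO` outranks it, leaving three models. The top model
says the mass–offspring slope steepens as June NAO falls (negative =
favourable weather): carry-over effects pay off only when breeding
conditions allow. Averaging over the retained trio:

```r
model_average(tab, coefs = ref)
#>        term natural_avg unconditional_se shrinkage_avg importance
#> 1 intercept -0.14608360               NA   -0.14608360  1.0000000
#> 2      mass  0.05645623               NA    0.05429858  0.9617820
#> 3       nao -0.67814629               NA   -0.67814629  1.0000000
#> 4  mass_nao -0.29000000               NA   -0.12445213  0.4291453
#> 5     mass2 -0.14000000               NA   -0.07456914  0.5326367
#> 6 mass2_nao -0.27000000               NA   -0.14381191  0.5326367
```

NAO carries weight 1 with a strongly negative averaged coefficient (−0.68
per SD of detrended NAO, log scale); the interaction terms are negative —
high mass helps most in good years. (Unconditional SEs appear when
averaging fitted models, which carry per-model SEs; the shipped reference
table has coefficients only.)

A fully synthetic end-to-end run, from generated captures to MCMC
predictions:

```r
cfg  <- sim_config(seed = 7)                    # 213 birds, 6 years
res  <- run_all(pipeline_config(out_dir = "run", seed = 7, simulate = cfg,
                                mcmc = mcmc_control(20000, 5000, 15)))
res$selection                 # AICc table on the synthetic data
res$grid                      # posterior predicted counts, good vs poor June NAO
```

There is also a thin CLI (`exec/carrygoose`) with `simulate`, `preprocess`,
`fit`, `select`, `bayes`, `report` and `run-all` subcommands over the same
functions.

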