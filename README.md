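# hetlogit

Mixed logit models with flexible mixing distributions and sequential
latent-class model averaging, for analysts of health discrete-choice
data who want to test — rather than assume — the standard practice of
giving every taste coefficient a normal distribution.

## What it does

The panel mixed logit integrates taste heterogeneity out of the choice
probabilities by simulation,

    P_n = (1/R) Σ_r Π_t P_ntj*(β_r),    LL = Σ_n ln P_n,

with per-coefficient mixing distributions drawn from eight families:
fixed, normal (S), uniform (U), triangular (T), log-normal (LN),
log-uniform (LU), asymmetric triangular (AT), and second/third-order
polynomial expansions (FM2, FM3). Estimation is maximum simulated
likelihood over modified Latin hypercube (MLHS) draws with analytic
gradients in a compiled core. Around that engine the package provides:

* **WTP space**: `V = β_p (price + Σ w_k x_k + ASCs)`, so
  willingness-to-pay amounts and their confidence intervals are
  estimated directly (`wtp_means()`);
* a **bivariate revealed-preference logit** with an individual error
  component shared across two binary outcomes (`fit_rp()`), capturing
  correlated product use;
* **sequential latent-class model averaging** (`fit_model_average()`):
  constituent fits are frozen and only logistic weights are estimated,
  so the average needs nothing but each model's person likelihoods and
  never fits worse than its best constituent; its AIC conservatively
  counts all constituent parameters;
* **post-estimation**: sample enumeration of choice shares,
  unconditional preference/WTP distributions with density summaries,
  and AIC-ordered comparison tables;
* a **synthetic-data module** that simulates the drug-choice experiment
  (1,000 persons x 10 tasks, 2 branded + 2 unbranded alternatives,
  bimodal branded taste) and correlated binary outcomes, recording the
  full generating truth for recovery tests;
* a **pipeline** (`cmd_simulate`/`cmd_fit`/`cmd_average`/`cmd_report`,
  plus `inst/cli/hetlogit-pipeline.R`) that runs
  simulate → fit all specifications → average → report from a YAML/JSON
  config.

## Worked example

```r
library(hetlogit)

sim   <- simulate_drug_dce(n_persons = 300, n_tasks = 10, seed = 7)
fit_S   <- fit_msl(drug_model_spec("S"),   sim$data, R = 100, seed = 1)
fit_FM2 <- fit_msl(drug_model_spec("FM2"), sim$data, R = 100, seed = 1)
ma <- fit_model_average(list(S = fit_S, FM2 = fit_FM2))

compare_models(list(S = fit_S, FM2 = fit_FM2, MA = ma))
#>   model        LL n_params      AIC      BIC
#> 1   FM2 -2920.728       21 5883.456 5961.236
#> 2     S -2942.548       14 5913.097 5964.949
#> 3    MA -2920.728       36 5913.456       NA

sample_enumeration(fit_S)
#>   branded unbranded
#>     0.412     0.588
```

The flexible polynomial specification beats the all-normal model by 22
log-likelihood units on data whose branded taste is genuinely bimodal,
and the model average puts all its weight on it (`ma$pi` is 0 / 1).
Predicted shares barely move across specifications — enumeration
reproduces the observed branded share either way — which is exactly the
pattern that makes fit, not forecasts, the interesting comparison.

The averaged unconditional distribution recovers the shape the normal
cannot:

```r
u  <- sample_unconditionals(ma, S = 10000, seed = 2)
ds <- density_summary(u$branded)
ds$share_positive   # 0.395 — most people dislike branded at these prices
ds$modes            # -3.3, -0.96, 0.65: multimodal, unlike any normal fit
```

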