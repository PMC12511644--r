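---
title: "Random preference heterogeneity: models, mixing distributions, and model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random preference heterogeneity: models, mixing distributions, and model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Discrete choice models in health economics almost always represent random
preference heterogeneity with a mixed (random parameters) logit in which
every taste coefficient is normally distributed. That convention is a
modelling *choice*, not a fact about preferences: tastes may be skewed,
strictly signed, bounded, or multimodal, and the normal family can
represent none of those shapes. `hetlogit` implements the comparative
machinery needed to take that question seriously: one estimation engine
that accepts seven parametric mixing families plus fixed coefficients,
willingness-to-pay (WTP) space estimation, a correlated-error bivariate
logit for revealed-preference outcomes, sequential latent-class model
averaging over fitted models, and a synthetic-data module that generates
choice panels with *known* taste distributions so every claim can be
tested end to end.

## Model

Utility for person $n$, task $t$, alternative $i$ is
$U_{nti} = V_{nti} + \varepsilon_{nti}$ with type-I extreme value errors,
so task-level choice probabilities are multinomial logit,
$P_{nti} = e^{V_{nti}} / \sum_j e^{V_{ntj}}$, and a person's panel
contribution is the product over their tasks of the chosen alternatives'
probabilities. Tastes $\beta_n$ vary across persons according to
per-coefficient mixing distributions; the likelihood integrates over
them, here by simulation:

$$P_n = \frac{1}{R} \sum_{r=1}^{R} \prod_t P_{ntj^*}(\beta_{nr}), \qquad
LL = \sum_n \ln P_n .$$

The draw-averaging happens around the *panel product* (tastes are fixed
within a person across tasks), not task by task — tastes vary across
individuals, not across choice occasions.

### Mixing families

Each coefficient is transformed from primitive standard-normal or
standard-uniform draws:

| family | transform | support |
|---|---|---|
| normal | $\mu + \sigma d_N$ | unbounded |
| uniform | $a + b\,d_U$ | $[a, a+b]$ |
| triangular | $a + b(d_{U1} + d_{U2})$ | $[a, a+2b]$ |
| log-normal | $s\,e^{\mu + \sigma d_N}$ | one-signed |
| log-uniform | $s\,e^{a + b\,d_U}$ | one-signed, bounded |
| asymmetric triangular | two-piece inverse CDF, mode $(a+b)/2 + c$ | $[a, b]$ |
| fm2 / fm3 | $\mu + \sum_{p \le P} \sigma_p u^p$ | bounded, flexible |

Numerical notes on three deliberate choices:

* **Triangular.** The sum-of-two-uniforms construction spans
  $[a, a+2b]$ with mode $a+b$. We implement and document exactly that
  transform; `b` is a *half-range*.
* **Asymmetric triangular.** Conditional on the piece, a triangular
  density is the square-root inverse CDF, so the lower piece is
  $a + (m-a)\sqrt{d_{U1}}$ and the upper $b - (b-m)\sqrt{d_{U2}}$ with
  $m = (a+b)/2 + c$; the piece is selected with probability equal to
  each piece's triangle area, using a third dedicated uniform. This is
  the unique construction that yields a proper triangular density and
  collapses exactly to the symmetric triangular at $c = 0$ — a property
  the test suite verifies by Kolmogorov–Smirnov distance. A linear
  (non-square-root) piece map mixed with area weights would instead
  produce a uniform density, so it is not used.
* **Polynomial expansions (fm2/fm3).** A single uniform per person-draw
  enters as powers $u, u^2, \dots$; the $\sigma_p$ are unconstrained in
  sign. These parameters are identified only up to the reflection
  $u \to 1-u$, which maps $(\mu, \sigma_1, \sigma_2)$ to
  $(\mu+\sigma_1+\sigma_2,\, -(\sigma_1+2\sigma_2),\, \sigma_2)$ without
  changing the coefficient's distribution. Recovery tests therefore
  compare estimates against the generating values *and* their
  reflection image.

### Scale parameters and boundaries

All scale parameters ($\sigma$, ranges $b$) are optimized on the log
scale with a floor of $10^{-8}$, so heterogeneity can shrink to an
effectively-zero boundary without sign flips or label switching. A fit
that ends on the floor is flagged as a boundary solution. Near the
boundary the log-likelihood is extremely flat in $\log \sigma$ (the
score is proportional to $\sigma^2$), so point estimates of very small
standard deviations are weakly identified; judge degeneracy by the
likelihood, not the raw $\hat\sigma$.

### Draws

The mixing integral uses modified Latin hypercube sampling (MLHS): for
each person and each coefficient dimension, the $R$ draws are a
randomly permuted equidistant grid shifted by a single uniform, so the
draws stratify $(0,1)$ perfectly. One master seed drives everything;
each (person, dimension) pair consumes its own substream in a fixed
order, so a person's draws do not depend on how many persons follow.
Default $R = 500$; the bivariate revealed-preference model defaults to
$R = 100$, where fewer draws empirically stabilize estimation on sparse
binary outcomes. Tests and examples use $R$ between 50 and 100, which
keeps simulated-likelihood noise well below the parameter-recovery
tolerances used there.

### WTP space

With a designated price coefficient $\beta_p$, utility is estimated as
$V = \beta_p\,( \text{price} + \textstyle\sum_k w_k x_k + \text{ASCs})$,
so the non-price parameters $w_k$ are money-denominated and their means
and confidence intervals come directly from the fit
(`wtp_means()`, delta-method 95% normal-theory CIs by default). Note
the sign convention this bracket implies: with $\beta_p < 0$, an
attribute people *like* carries a *negative* $w_k$. The bracket form is
implemented literally; negate $w$ if you prefer to report
willingness-to-pay with the opposite sign convention.

### Revealed-preference bivariate logit

Two binary outcomes (cigarette and e-cigarette use) are logits sharing
one individual error component $\rho_n \sim N(0, \sigma_\rho^2)$:
$P_{cig} = \Lambda(V_{cig} + \rho_n)$,
$P_{ecig} = \Lambda(V_{ecig} + s\rho_n)$ with $s = \pm 1$ choosing the
direction of the induced correlation. The person likelihood averages
$P_{cig}^{c}(1-P_{cig})^{1-c}P_{ecig}^{e}(1-P_{ecig})^{1-e}$ over
$\rho$ draws — the complement must enter the final factor for the
expression to be a probability for e-cigarette non-users. $\rho_n$ is
taken normal with $\sigma_\rho \ge 0$ estimated on the log scale.

### Sequential latent-class model averaging

$K$ fitted models are frozen; only the weight parameters $\theta_k$ of
the logistic weights $\pi_k = e^{\theta_k}/\sum_j e^{\theta_j}$ are
estimated by maximizing $\sum_n \ln \sum_k \pi_k P_{nk}$, which needs
nothing but each model's person-likelihood vector. Two identification
choices: $\theta_1 \equiv 0$ (the logistic form is over-parameterized),
and $|\theta_k| \le 30$ so degenerate averages (all weight on one
model) are representable without overflow and are reported as boundary
solutions. Because the constituents' likelihood columns are fixed, the
optimized average can never fit worse than its best constituent; the
implementation uses tight optimizer tolerances so this holds to
$10^{-6}$ log-likelihood units. The reported AIC is deliberately
*conservative*: it counts all parameters of all constituents plus the
$K-1$ weights. Standard errors for quantities derived from an average
ignore first-stage estimation noise; a corrected two-stage variance is
out of scope.

## Estimation engine

Maximum simulated likelihood via `stats::optim` (L-BFGS-B) with
*analytic* gradients: the C++ core returns, alongside $P_n$, the score
contributions
$\text{panelprod}_{nr} \cdot \sum_t (x_{k,\text{chosen}} - \sum_j P_{ntj} x_{k,j})$,
which the R side chains through each family's transform derivatives
(and through the WTP product rule). The analytic gradient matches
central finite differences to $10^{-7}$ in the test suite across all
eight families and both utility spaces. Default start values are the
MNL (all-fixed) estimates for location parameters with small positive
scales; estimation is deterministic given (seed, start, settings).
Convergence uses `factr = 1e8` — the simulated likelihood is flat to
well below draw noise at that point — with the Hessian computed as the
central-difference Jacobian of the analytic gradient and covariance
mapped to the natural scale by the delta method. Non-convergence and
boundary solutions are flagged on the fit object, never silently
dropped; the pipeline records failed specifications (flexible families
do sometimes fail on real data) and continues.

## What the synthetic-data module emulates

`simulate_drug_dce()` generates the drug-choice study design: 1,000
persons by default, 10 tasks, 4 alternatives (2 branded, 2 unbranded)
described by country of production, drug characteristic
(standard / fast acting / double strength), side-effect risk and price,
with tastes drawn once per person and choices generated by comparing a
single $U[0,1]$ draw per task against cumulative MNL probabilities.
The default generating distributions are frozen, documented choices —
a bimodal two-component normal mixture for the branded taste
($0.5\,N(-2.5, 0.5^2) + 0.5\,N(1.5, 0.5^2)$, chosen so the aggregate
branded share sits near 0.46, the published aggregate for this design),
normal country tastes, triangular and uniform characteristic tastes,
and strictly negative log-normal risk and price tastes. Attribute
levels (risk $\in \{1, 5, 10, 15\}$ percent, price
$\in \{1, \dots, 5\}$) are assigned to alternatives by independent
uniform sampling; constructing a D-optimal experimental design is out
of scope, and uniform assignment preserves identifiability. Every run
records the full truth (families, parameters, per-person tastes, seed).

What the generator does *not* emulate: real survey behaviour
(inattention, lexicographic rules, scale heterogeneity), blocked or
optimized designs, availability restrictions driven by realism, or
taste correlation across coefficients. Passing recovery tests on these
simulations therefore demonstrates internal consistency of the
estimator and the generator — not that any particular real dataset
satisfies the model's assumptions.

`simulate_rp_binary()` mirrors the revealed-preference structure
(shared error component, configurable association direction), and
`rp_composition_data()` reproduces a fixed sample composition
(cigarette-only / e-cigarette-only / dual / neither) exactly, which is
what makes the share-reproduction checks deterministic.

## Post-estimation

* **Sample enumeration** averages draw-level predicted probabilities
  over persons, tasks and draws, aggregated by alternative groups; a
  model average enumerates as the $\pi$-weighted mix of its
  constituents. With a full set of alternative-specific constants the
  logit score equations force enumerated shares to equal observed
  shares, which is why predicted shares are nearly invariant across
  mixing specifications.
* **Unconditionals** are pseudo-random draws from the *fitted*
  population-level mixing distributions (for an average: draw a
  constituent by weight, then draw from it). Density summaries use a
  Gaussian kernel with Silverman's bandwidth on a grid padded 5% beyond
  the sample range; degenerate samples are reported as point masses;
  local modes above 10% of the peak density are reported.
* **Model comparison** tables sort by AIC ($2k - 2LL$; BIC uses
  $k \ln N$ with $N$ = persons); the average's conservative parameter
  count is used there.

## Problem sizes in the test suite

The suite exercises recovery at 300 persons x 10 tasks with $R = 100$
(10 replicates per family), weight recovery at 1,000 persons, and the
bimodal-recovery comparison at 300 persons; these sizes give the
recovery checks comfortable power while keeping the whole suite around
two minutes on one core. The same properties hold at the full
1,000-person, $R = 500$ scale, just more slowly.

## Known limitations

* Fig-style uncertainty for model-average outputs ignores first-stage
  noise (see above).
* The polynomial families' reflection non-identification means raw
  parameter tables for fm2/fm3 should be read as one representative of
  an equivalence pair; derived quantities (densities, means, WTP) are
  unaffected.
* Boundary standard errors (scale parameters estimated near zero,
  weights at the cap) are unreliable; the objects flag these cases.
* Inter- and intra-respondent heterogeneity, correlated mixing
  distributions, latent-class and nonparametric mixtures are out of
  scope.
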