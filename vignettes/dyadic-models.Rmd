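---
title: "Dyadic models by covariance-structure ML: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic models by covariance-structure ML: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadfit)
```

## The modeling problem

Dyadic designs measure both members of a linked pair, so the two scores
per construct are correlated within dyads. With *distinguishable* dyads
(a meaningful role variable such as gender or patient/caregiver), the
standard analysis vocabulary is a four-variable system — predictor and
outcome per member — and three structural accounts of the
nonindependence:

* the **APIM**, where each predictor has an *actor* path to one's own
  outcome and a *partner* path to the other member's outcome;
* the **MIM**, where the outcomes influence each other directly
  (*dyadic feedback*), making the system nonrecursive; each predictor
  reaches the partner's outcome only through one's own outcome, so the
  cross-member effect is a mediated (indirect) effect;
* the **CFM**, where a shared dyad-level factor drives both members'
  scores and the causal path runs between latent variables.

All three are covariance-structure models: they constrain only the
covariance matrix of the observed variables, so the sufficient input is
`(n, SDs, correlations)` — means are saturated and carry no structural
information here. This is why a published descriptive table is a
complete dataset for these models, and why the package accepts
`summary_moments` objects wherever it accepts data.

## Estimation

Models are stored in RAM form (`path_model`): a directed-path matrix
$A$, a symmetric matrix $S$ of variances/covariances, and a filter $F$
selecting observed variables, with
$\Sigma(\theta) = F (I-A)^{-1} S (I-A)^{-\top} F^\top$. Free parameters
are labels; two entries sharing a label are one parameter, which is how
equality constraints are imposed (never by averaging estimates after the
fact). Degrees of freedom are $p(p+1)/2$ minus the number of distinct
labels.

Fitting minimizes $F_{ML}(\theta) = \ln|\Sigma| +
\mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$ and reports
$\chi^2 = N \cdot F_{ML}(\hat\theta)$. The multiplier $N$ is `n` by
default — the convention of the major SEM programs — with `n-1`
available (`n_mult = "n-1"`) for cross-checking against software that
rescales. Descriptive SDs and covariances use the conventional $n-1$
denominator throughout; the engine's multiplier choice absorbs the
difference. Standard errors come from the inverse of the numerically
differentiated Hessian of $N F_{ML}/2$ at the minimum (observed
information), $z = \hat\theta / SE$ is tested against the standard
normal (two-sided), matching the star conventions of mainstream SEM
output. Significance markers use \*, \*\*, \*\*\* at 0.05/0.01/0.001 and
† at 0.1; where a borderline within-person residual covariance is
marked, the two-sided convention is assumed.

### Numerical strategy

* **Start values.** For models with no latent variables the saturated
  system has a closed-form solution: paths from per-outcome moment
  equations (normal equations, or instrumental-moment equations with the
  exogenous variables as instruments when an outcome predicts an
  outcome), then the free $S$-entries read off
  $(I-A) S_{\mathrm{sample}} (I-A)^\top$. That solution *is* the start,
  so saturated fits converge in a step or two and constrained variants
  start close. Latent models start from moment proxies: a unit-loading
  latent's variance from the mean covariance among its indicators,
  indicator residuals from a fraction of the observed variances.
* **Optimization.** BFGS with the analytic RAM gradient, followed by
  damped Newton polishing until the gradient norm is below $10^{-10}$
  (the reported convergence criterion is $10^{-6}$). Outside the
  positive-definite region the objective returns a large penalty, so the
  line search retreats. Up to five deterministically jittered restarts
  are attempted on failure; determinism keeps reports byte-stable.
* **Degenerate cases.** A feedback product of 1 makes $I-A$ singular and
  is reported as an unstable loop naming the variable pair. Negative
  fitted variances are reported with a Heywood-case warning rather than
  a hard failure, and are clipped only where a variance ratio requires
  it (the CFM $R^2$). A saturated model whose remaining discrepancy is
  below $10^{-8}$ reports $\chi^2 = 0$ — the saturation identity, not a
  tolerance on misfit. An ill-conditioned information matrix falls back
  to a pseudo-inverse with a warning.

### Fit indices and model comparison

CFI, TLI, RMSEA ($\sqrt{\max(\chi^2-df,0)/(df\,n)}$, 0 by convention at
$df=0$) and SRMR (root mean square of standardized residuals over all
unique elements including the diagonal) are computed against an
independence baseline — all covariances fixed to zero, variances free —
whose $\chi^2$ has the closed form $-N\ln|R|$. This baseline is an
approximation to what commercial programs print; in the over-fitting
regime of the packaged study ($\chi^2 < df$ everywhere) the indices pin
at their ideal values and are insensitive to the choice. TLI is reported
capped at 1 with the raw value retained (`tli_raw`), since whether
published tables cap it is not generally determinable. Nested variants
are compared by $\Delta\chi^2$ with $\Delta df$ equal to the difference
in free-label counts; tiny negative differences (within $10^{-6}$) are
clipped to zero.

## Identification choices

The CFM is identified by fixing all four loadings to 1, which puts the
latents in the observed metric; the latent predictor variance, the
latent regression $b$, the latent residual, four indicator residuals and
two within-person residual covariances give 9 parameters and $df = 1$.
An alternative scaling (`scale_by_latent_variance = TRUE`) fixes both
latent (residual) variances to 1 and frees the loadings tied within
construct; scale-free quantities such as $\chi^2$ and the explained
variance $R^2 = b^2\phi/(b^2\phi+\psi)$ agree between the two scalings,
which the test suite checks.

For the hypothesis battery, the partner-effect verdict is reported two
ways: per direction from the saturated model, and on the pooled
partner-equal model. With these data one direction is individually
nonsignificant while the pooled effect is clearly present; basing the
headline decision on the pooled estimate mirrors how such batteries are
commonly read, and both views are retained in the report's details.

## The synthetic generator

`generator_spec()` defines a population with known APIM, MIM or CFM
structure and `simulate_dyads()` draws exact multivariate-normal dyads
from its implied covariance (Cholesky transform of a seeded
standard-normal matrix; bit-reproducible per seed, with per-replicate
seeds derived as `seed + counter` in experiments). The MIM population is
assembled through the reduced form $Y = (I-B)^{-1}(\Gamma X + e)$ — an
independent route that the tests check against the RAM identity — and
requires $|b_{12}b_{21}| < 1$ for stability.

Default population values echo the packaged study's regime (predictor
SDs near 4.3–4.5, outcome SDs near 6.6, actor effects near −0.45,
predictor covariance 4, CFM latent effect −1.4 with latent variance 4),
so recovery experiments resemble the data the package is built around.
The generator emulates exactly multivariate-normal, complete,
continuous dyad scores. Real questionnaire data are bounded integer sum
scores with possible skew, floor/ceiling effects and missingness; none
of that is emulated, so passing recovery tests certify the estimator
under its own assumptions, not robustness to violations of them.
Gaussian data are the ML estimator's assumption; heavy-tailed stress
tests are a possible extension, not a default.

## Validation design and problem sizes

The test suite validates at these scales, chosen to make Monte-Carlo
error small relative to the assertion margins while keeping the default
run in the minutes range: moment-convergence checks at $n = 50{,}000$
(3 MC SEs), consistency checks at $n = 10{,}000$ (2 MC SEs), recovery
experiments with 500 replicates at $n = 1{,}000$ per framework, and the
actor-equality type-I-error calibration with 1000 replicates at the
study's own $n = 141$ (rejection rate checked against the 0.03–0.07
band at $\alpha = 0.05$).

## Known limitations

* The CFM latent regression, a ratio-type estimator, shows a small
  finite-sample skew in the default (study-like, weakly identified)
  regime: the recovery experiment measures a bias of about $-0.04$ on a
  true effect of $-1.4$ at $n = 1{,}000$, shrinking to about $-0.004$ by
  $n = 4{,}000$. The estimator is consistent; at moderate dyad counts
  its point estimate is slightly too large in magnitude, and the
  corresponding recovery assertion in the acceptance tests documents
  this by failing the 0.02 bias bound for the CFM path.
* Missing data are handled by listwise deletion (rows are flagged, not
  dropped, at the table level); full-information ML is out of scope.
* Indistinguishable-dyad methods, multilevel estimation of the APIM,
  robust/weighted estimators, bootstrapped SEs and ordinal-indicator
  models are out of scope.
* Printed correlation tables are accepted at their printed precision;
  reconstructed covariance matrices inherit that rounding, which moves
  $\chi^2$-scale quantities by a few thousandths (e.g. an equality-test
  $\Delta\chi^2$ of 0.006 where full-precision data gave 0.004).

## Scale scoring

`score_scale()` recodes reverse-keyed items as $\min + \max - x$ (the
standard recode; sources often say only "recoded") and sums;
`cronbach_alpha()` uses sample variances with the $n-1$ denominator and
equals $k\bar r/(1+(k-1)\bar r)$ under compound symmetry, which the
tests verify against data carrying exact sample moments.
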