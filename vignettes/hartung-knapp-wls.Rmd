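---
title: "Random-effects meta-analysis as weighted least squares: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-effects meta-analysis as weighted least squares: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkmeta)
```

## The model

The package fits the normal-normal random-effects model for $n$ independent
study-level effect estimates $y_i$:

$$y_i = \mu + \varsigma_i + \delta_i, \qquad
  \varsigma_i \sim N(0, \tau^2), \qquad \delta_i \sim N(0, v_i),$$

with all $\varsigma_i, \delta_i$ mutually independent.  The within-study
sampling variances $v_i$ are estimated upstream (see the effect-size
converters below) and then treated as known — the standard meta-analytic
convention.  Two parameters remain: the average effect $\mu$ and the
between-study variance $\tau^2$.  Meta-regression generalises $\mu$ to
$\beta_0 + \sum_j \beta_j x_{ij}$ for study-level moderators $x_{ij}$, and
$\tau^2$ becomes the *residual* between-study variance.

After estimating $\tau^2$, both supported inference methods pool with the
inverse-variance weights $w_i^* = 1/(v_i + \hat\tau^2)$, giving the shared
point estimate $\hat\mu = \sum w_i^* y_i / \sum w_i^*$ and the conventional
variance $V = 1/\sum w_i^*$.

## Two pivots, two WLS models

**Conventional.**  Treating every variance as known makes
$(\hat\mu - \mu)/\sqrt{V}$ a standard normal pivot; the CI is
$\hat\mu \pm z_{\alpha/2}\sqrt{V}$.

**Hartung-Knapp.**  The variance of $\hat\mu$ is instead estimated by
$H^{*2} V$, where

$$H^{*2} = \frac{\sum w_i^* (y_i - \hat\mu)^2}{n-1}$$

is the weighted mean squared error of the fit, and the pivot
$(\hat\mu - \mu)/\sqrt{H^{*2} V}$ is referred to $t_{n-1}$.

The package treats the following regression view as primary.  An
intercept-only weighted least squares model with weights $w_i^*$ and error
variances *known* to be $1/w_i^*$ reproduces the conventional method
exactly: $\hat\beta = \hat\mu$, $\mathrm{Var}(\hat\beta) = V$, normal
reference.  The same model with error variances known only *up to a
proportionality constant* $k$ — the assumption every standard regression
package makes — estimates $k$ by the weighted MSE with $n-p$ degrees of
freedom and uses $t_{n-p}$; for $p = 1$ the estimate is exactly $H^{*2}$
and the procedure is exactly the Hartung-Knapp method.  The identity
$\hat k = H^{*2}$ is the hinge of the package: it is asserted by
`equivalence_report()`, which runs the meta-analytic formulas and a generic
`stats::lm` weighted fit on the same data and diffs every reported quantity
at tolerance $10^{-8}$ (the agreement is algebraic, so observed
discrepancies are rounding noise near $10^{-16}$).

For meta-regression the same two regressions apply with the full design
matrix; $H^{*2}$ generalises by replacing $\hat\mu$ with the fitted values
and dividing by $n - p$, and inference is per coefficient (no omnibus
F-test is provided — interest in practice is in individual moderators, and
the per-coefficient table is what the equivalence concerns).

## Constrained scaling factors

$H^{*2}$ estimates a quantity that is approximately 1 when the variance
components are well estimated, yet it can take any positive value; small
values produce Hartung-Knapp intervals *shorter* than conventional ones,
which is unpalatable given that the conventional method already ignores
estimation uncertainty.  `hk_inference()` therefore exposes three modes:

* `none` (default): the unconstrained method.
* `unit`: scale factor $\max(H^{*2}, 1)$ — the HK interval is then always
  at least as wide as the conventional one; conservative.
* `zt`: scale factor $\max(H^{*2}, (z_{\alpha/2}/t_{n-1,\alpha/2})^2)$ —
  algebraically equivalent to reporting the wider of the conventional and
  unconstrained HK intervals, hence less conservative than `unit`.  The
  width identity $\mathrm{width}_{zt} = \max(\mathrm{width}_{conv},
  \mathrm{width}_{HK})$ holds to machine precision and is tested.

The defaults deliberately leave constraints off: they are adjustments a
user should opt into, and the unconstrained method is the reference point
for all equivalences above.

## Estimating the between-study variance

`tau2_reml()` maximises the restricted log-likelihood

$$\ell_R(\tau^2) = -\tfrac12\left[(n-p)\log 2\pi + \sum_i \log(v_i+\tau^2)
  + \log\lvert X^\top W X\rvert + r^\top W r\right]$$

over $\tau^2 \in [0, B]$ with $B = 10(\max y_i - \min y_i)^2 + \max v_i$, a
bound comfortably above any plausible maximiser (the restricted likelihood
decays once $\tau^2$ exceeds the dispersion of the data).  The search is a
201-point bracketing grid followed by golden-section refinement to an
absolute tolerance of $10^{-8}$, capped at 200 iterations; the returned
object carries the iteration count and a convergence flag rather than
failing silently.  Estimates are truncated at exactly 0 whenever the
boundary value of the likelihood is at least as high as the interior
candidate.  A bounded scalar search was chosen over derivative-based
iterations because the profile surface is one-dimensional, cheap, and the
grid stage makes the search robust to flat or boundary-maximised surfaces;
any maximiser of the same restricted likelihood is statistically
equivalent.  Tests verify the result against a dense $10^{-5}$-step grid
search of the same likelihood (independent code) and against
`metafor::rma.uni`.

`tau2_dl()` provides the DerSimonian-Laird moment alternative, in its
generalised form for arbitrary designs
$\hat\tau^2 = \max\{0, (Q - (n-p)) / (\mathrm{tr}(W_0) -
\mathrm{tr}((X^\top W_0 X)^{-1} X^\top W_0^2 X))\}$ with fixed-effect
weights $W_0 = \mathrm{diag}(1/v_i)$.  REML is the default everywhere.
For meta-regression, $\tau^2$ is estimated under the **full covariate
model** and then held fixed in the weights; estimating it under the
intercept-only model would conflate moderator effects with heterogeneity.

## Effect-size conversion

Two converters cover the common raw inputs:

* `hedges_g(d, n1, n2)`: Cohen's $d$ with
  $v_d = (n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$, multiplied by the
  **exact** small-sample correction
  $J(m) = \Gamma(m/2)/(\sqrt{m/2}\,\Gamma((m-1)/2))$ at $m = n_1+n_2-2$
  degrees of freedom ($g = Jd$, $v_g = J^2 v_d$).  $J$ is computed via
  log-gamma differences so it cannot overflow for large $m$; the familiar
  $1 - 3/(4m-1)$ approximation agrees to about $10^{-4}$ at $m = 18$ but
  there is no reason to prefer it numerically.
* `log_odds_ratio(a, b, c, d)`: $y = \log(ad/bc)$,
  $v = 1/a + 1/b + 1/c + 1/d$.  Tables containing a zero cell get 0.5
  added to **all four cells of that table only** — the standard continuity
  convention; untouched tables keep their exact counts.  A correction of 0
  turns zero cells into a hard error instead of a silent `Inf`.

## The simulator and what it does (not) show

`simulation_spec()` / `generate_meta_dataset()` draw directly from the
model above: $y_i = \mu + N(0,\tau^2) + N(0, s_i^2)$ with `vi` reported as
the *true* $s_i^2$.  Defaults follow the settings used throughout the
package's own checks: $10^4$ replications (Monte Carlo SE of a coverage
proportion near 0.95 is then $\approx 0.0022$, so a $3\,$SE band is about
$\pm 0.0065$), $\alpha = 0.05$, REML, unconstrained HK.  Each
replication's random stream is derived from `(seed, rep_index)` by a pair
of Lehmer mixing steps, so datasets are reproducible individually and
methods can be compared on **shared streams** (`compare_methods()`), where
the interval-containment orderings between `zt`, `unit`, unconstrained HK
and conventional intervals hold replication by replication, not merely on
average.

The headline simulation exercises the one setting with an analytic answer:
with all within-study variances equal, the weights are equal *whatever*
$\hat\tau^2$ is, $\hat\mu$ is the plain mean, $H^{*2}V$ is the sample
variance of the $y_i$ over $n$, and the HK pivot **is** the one-sample $t$
statistic of i.i.d. normal draws — so 95% coverage is exact, REML noise
notwithstanding.  Similarly, with $\tau^2$ supplied as known, the
conventional $z$ pivot is exact even under unequal $s_i^2$.

What the simulator does **not** emulate: estimated (noisy) within-study
variances, correlation between $v_i$ and $y_i$ (both common with small
primary studies), non-normal random effects, and publication selection.
Passing coverage tests therefore demonstrate correctness of the
implementation under the model, not robustness of the methods on real
data.

Degenerate replications — all $y_i$ equal to $\hat\mu$, so $H^{*2} = 0$
and the unconstrained HK interval has zero width — are flagged
(`degenerate = TRUE`), counted, and kept in the coverage denominator;
dropping them would bias coverage upward.  They are practically impossible
under continuous data but can occur with user-supplied degenerate input.

## Numerical and interface choices

* p-values are two-sided throughout; default $\alpha = 0.05$.
* $n = 2$ studies is allowed for HK inference (df = 1) with a warning —
  the method defines it, but the interval is enormous.
* Design matrices must be full column rank, checked via the singular-value
  ratio at $10^{-10}$; categorical moderators must arrive pre-coded as 0/1
  dummies (the readers keep any extra numeric CSV columns as covariates).
* WLS solves go through the QR decomposition of $\sqrt{w}$-scaled data
  rather than the normal equations.
* JSON/TSV output keeps full floating precision (17 significant digits, so
  parsing reproduces every number bit-exactly); only the human-readable
  text view rounds, to 3 decimals.
* Worked-example reproduction: the package's checks include reproducing a
  published 10-study standardized-mean-difference meta-analysis (open vs
  traditional education, Hedges & Olkin 1985, Table 9) and a 16-trial
  pneumococcal-vaccine meta-regression with two dummy moderators, both to
  3 printed decimals.  Those primary datasets are not redistributable
  within the package, so the corresponding test asks for user-supplied
  CSVs under `inst/extdata/` and fails informatively when absent.

## Known limitations

Fixed-effect analysis is available only implicitly (`tau2 = 0`);
prediction intervals, $\tau^2$ confidence intervals, Paule-Mandel and
other $\tau^2$ estimators, robust/sandwich variances, permutation tests,
multivariate generalisations, and plotting are out of scope.  The
normal-within-study approximation is inherited from the model: for sparse
binary data a generalised linear mixed model would avoid it, at the cost
of changing the estimand and losing the WLS correspondence that this
package is about.
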