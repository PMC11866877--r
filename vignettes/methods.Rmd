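---
title: "Methods: non-inferiority for binary matched pairs with missing values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-inferiority for binary matched pairs with missing values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nipaired)
```

# Setting and notation

Each of $n$ patients receives both interventions and contributes a pair of
binary outcomes $(y_{1}, y_{2})$. Write $p_j = P(y_j = 1)$ and let
$\theta = p_1 - p_2$ be the risk difference. With a non-inferiority margin
$\delta > 0$ the hypotheses are

$$H_0:\ \theta \le -\delta \qquad \text{vs.} \qquad H_1:\ \theta > -\delta,$$

tested at one-sided level $\alpha$ (default $0.05$). All methods in the
package use the *uniform decision rule*: compute a two-sided
$100(1-2\alpha)\%$ confidence interval for $\theta$ and reject $H_0$ exactly
when its lower bound exceeds $-\delta$. With the defaults this is a 90%
interval. Comparing interval methods under this rule compares them on a
common decision surface: type-I error at the boundary $\theta = -\delta$,
power in the interior, and two-sided coverage are all properties of the same
interval.

Complete pairs fall into the familiar $2\times2$ cells $n_{00}, n_{01},
n_{10}, n_{11}$ (first index = outcome under intervention 1). When single
observations can be missing the observable data form a $3\times3$ table with
an additional missing category `x` on each margin: $n_{0x}, n_{1x}$ count
pairs with the second outcome missing and $n_{x0}, n_{x1}$ pairs with the
first outcome missing. Pairs with *both* outcomes missing carry no
information about $\theta$ and are rejected at input. The package assumes
missingness is (at most) MAR — the probability that one outcome is missing
may not depend on unobserved values.

The complete-case estimator is
$\hat\theta_{cc} = (n_{10} - n_{01}) / n_{++}$ with
$n_{++}$ the number of complete pairs; the all-observed estimator used by
the hybrid and GEE methods estimates each margin from every observed
outcome, e.g. $\hat p_1 = (n_{1+} + n_{1x})/(n_{++} + n_{+x})$.

# Score test and score interval (complete cases)

The score test of $H_0$ standardizes $\hat\theta_{cc} + \delta$ by the null
variance evaluated at the *restricted* maximum-likelihood estimate: with
$\hat q = n_{01}/n_{++}$, the null RMLE of the $(0,1)$-discordant
probability $p_{01}$ under the boundary $\theta = -\delta$ is the
admissible root of the quadratic $2x^2 + a_1 x + b_1 = 0$ with

$$a_1 = -\hat\theta_{cc}(1 - \delta) - 2(\hat q + \delta), \qquad
b_1 = \delta(1 + \delta)\,\hat q,$$

i.e. $\tilde p_{01} = (-a_1 + \sqrt{a_1^2 - 8 b_1})/4$, and the null
variance is $\tilde\sigma_0^2 = (\tilde p_{01} + \tilde p_{10} -
\delta^2)/n_{++}$ with $\tilde p_{10} = \tilde p_{01} - \delta$. (The tests
verify that the root satisfies the quadratic to $10^{-10}$.) The one-sided
test rejects when the standardized score exceeds $z_{1-\alpha}$. At
$\delta = 0$ the squared statistic reduces exactly to McNemar's $\chi^2$
without continuity correction.

`tango_ci()` inverts the two-sided version of this statistic: the interval
endpoints are the values $\theta_0$ at which the standardized score equals
$\pm z_{1-\alpha}$. Each endpoint is found with `uniroot()` (Brent's method,
tolerance $10^{-10}$) on $(-1, 1)$, after bracketing by the sign of the
score; this is robust because the standardized score is monotone in
$\theta_0$. Degenerate tables (no discordant pairs, or all discordant pairs
in one cell) are handled by the same inversion and give the expected
one-sided or symmetric limits. The test and interval are *dual* by
construction — `nam_test(tab, delta)$reject` always equals
`noninferior(tango_ci(tab), delta)` — and this duality is exercised on a
thousand random tables in the test suite.

## Asymptotic power and sample size

`nam_power()` evaluates the standard normal approximation

$$\mathrm{power}(n) = \Phi\!\left(\frac{(\theta + \delta)\sqrt{n}
  - z_{1-\alpha}\,\tilde\sigma_0}{\sigma_a}\right),$$

where $\tilde\sigma_0$ is the null standard deviation at the RMLE under the
boundary and $\sigma_a$ the standard deviation under the alternative, both
per-$\sqrt n$. `nam_samplesize()` returns the smallest integer $n$ reaching
the target power. For a design with $p_1 = p_2 = 0.8$, within-pair
correlation $\rho = 0.375$ (equivalently a concordant-pair probability of
$0.8$), $\delta = 0.05$, $\alpha = 0.05$ and 80% power this gives
$n = `r nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05)`$ complete
pairs. Because the score method discards incomplete pairs, a missingness
rate of $q_j$ on each outcome ($q_1 = q_2 = 0.1$, so 20% of patients lose
one observation) inflates the requirement to
$\lceil n / (1-q_1-q_2) \rceil =
`r nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05,
                  p_missing = c(0.1, 0.1))`$ patients.

# Multiple imputation (Wald)

`mi_ci()` imputes each missing outcome from a saturated logistic regression
of the missing outcome on the observed one, fitted on the complete pairs —
e.g. $y_1 \mid y_2 = k$ is Bernoulli with logit equal to the group log-odds.
Because the models are saturated, the fits have closed form: the coefficient
posterior is normal with mean the empirical logit and standard deviation
$\sqrt{1/a + 1/b}$ for cell counts $a, b$ (a Haldane correction of $+0.5$ is
applied to zero cells, with a warning). For each of $m = 10$ imputations the
parameters are drawn from this approximate posterior, missing outcomes are
drawn from the implied Bernoulli laws, and the completed table yields the
standard paired Wald estimate and variance
$\hat\sigma^2 = \{(\hat p_{01} + \hat p_{10}) - \hat\theta^2\}/n$. Rubin's
rules pool the $m$ estimates: total variance $= W + (1 + 1/m)B$ with $W$ the
mean within-imputation variance and $B$ the between-imputation variance; a
Barnard–Rubin $t$ reference is available via `use_t = TRUE` (the default
uses the normal reference, matching the large designs the method targets). On a table with no missing values the procedure collapses
exactly to the single complete-data Wald interval.

# Hybrid interval (Wilson-based)

`hybrid_ci()` forms the Wald-type interval
$\hat\theta \pm z_{1-\alpha}\,\widehat{se}$ on the all-observed margin
estimates, but estimates the variance from *back-solved Wilson intervals*:
for each margin the two-sided $100(1-2\alpha)\%$ Wilson score bounds
$(l_j, u_j)$ are computed from all observed outcomes of that arm, and the
variance of each $\hat p_j$ near the relevant bound is recovered as
$(\hat p_j - l_j)^2/z^2$ or $(u_j - \hat p_j)^2/z^2$ (a MOVER-style
combination). The within-pair dependence enters through the sample phi
coefficient of the complete pairs, so the lower bound of the difference is

$$L = \hat\theta - \sqrt{(\hat p_1 - l_1)^2 + (u_2 - \hat p_2)^2
  - 2\hat\phi\,(\hat p_1 - l_1)(u_2 - \hat p_2)}$$

and symmetrically for the upper bound. If a radicand turns (numerically)
negative it is clipped at zero with a warning. With $\hat\phi = 0$ the
formula reduces to the independent-samples MOVER interval, an identity the
tests verify to $10^{-12}$ on a table with exactly zero sample correlation.

# GEE (marginal logistic model)

`gee_fit()` treats each patient as a cluster of up to two binary
observations and fits the marginal logistic model

$$\mathrm{logit}\, P(y_{ij} = 1) = \beta_0 + \beta_1 x_{ij},$$

with $x_{ij}$ the intervention indicator, an exchangeable working
correlation and fixed scale $\phi = 1$. Patients with one missing outcome
contribute singleton clusters, so all observed data are used. The working
correlation is the moment estimator of the Pearson-residual cross product
over complete clusters (denominator $\max(n_{++} - 2, 1)$). Because the
design matrix takes only a handful of distinct values, the estimating
equations reduce to functions of the eight observable cell counts, and the
package solves them by Fisher scoring on those sufficient counts — the
result is verified in the tests against a brute-force per-cluster matrix
loop (score $< 10^{-6}$, covariances to $10^{-8}$). Complete separation
(an arm with all-0 or all-1 observed outcomes) is detected and raised as an
error rather than returning a divergent fit.

The risk difference is $g(\beta) = \mathrm{expit}(\beta_0) -
\mathrm{expit}(\beta_0 + \beta_1)$, with standard error from the delta
method, $\widehat{se} = \sqrt{g'(\hat\beta)^\top \widehat{\mathrm{Cov}}
(\hat\beta)\, g'(\hat\beta)}$, using the **full** $2 \times 2$ robust
(sandwich) covariance $I_0^{-1} I_1 I_0^{-1}$ by default
(`robust = FALSE` selects the model-based $I_0^{-1}$). `gee_ci()` is then
the Wald interval $g(\hat\beta) \pm z_{1-\alpha}\,\widehat{se}$.

# Simulation machinery

`joint_from_marginals(p1, p2, rho)` converts marginals and a within-pair
correlation to the joint cell probabilities
$p_{11} = p_1 p_2 + \rho\sqrt{p_1(1-p_1)p_2(1-p_2)}$ etc., validating the
Fréchet bounds. `generate_pairs()` draws pair-level data;
`impose_missing(pairs, q1, q2)` draws one trinomial indicator per pair —
delete outcome 1 with probability $q_1$, delete outcome 2 with probability
$q_2$, keep both otherwise — so the per-outcome missingness rates are
exactly $(q_1, q_2)$ and no pair ever loses both outcomes. Deletion never
depends on the outcome values, so the mechanism is MCAR when $q_1 = q_2$
and arm-dependent (hence still covered by the MAR assumption) when the
rates differ. Internally the study harness uses an equivalent
count-level generator (multinomial cells plus binomial missingness splits),
which the tests verify is distributionally identical to the pair-level path.
The generator is deliberately simple — exchangeable correlation, homogeneous
missingness — and does not model covariates, clustering beyond the pair, or
MNAR mechanisms.

`run_scenario()` evaluates, per replicate and method, rejection of $H_0$ and
coverage of the true $\theta$ by the 90% interval, and reports Monte-Carlo
standard errors $\sqrt{\hat p(1-\hat p)/n_{\mathrm{eval}}}$. Replicates on
which a method fails (e.g. GEE separation in very small samples) are
excluded from that method's denominator and counted in `n_failed`, with a
warning when they exceed 1% of replicates. Scenario parameters map signs as
follows: the base rate is $0.8$; at true difference $\theta$ the marginals
are $p_1 = 0.8 + \min(\theta, 0)$ and $p_2 = 0.8 - \max(\theta, 0)$, so the
boundary scenario $\theta = -\delta$ lowers $p_1$. All randomness flows from
a root seed through deterministic substreams (`derive_seed`), separating the
data-generation, missingness and imputation streams, so that e.g. adding a
method to a scenario leaves the other methods' results bit-identical.

`sample_size_search()` runs a scenario at each value of an `n` grid with
common random numbers and selects the smallest $n$ whose estimated power
exceeds the target *at that n and at every larger grid value* — a
conservative rule that is robust to single Monte-Carlo dips of the estimated
power curve.

# Default study grid and scaled problem sizes

`scenario_grid()` spans 13 sample sizes ($n = 20$–$100$ by 10, then 200,
300, 400, 507), $\rho \in \{0, 0.37, 0.5\}$, three margin/effect
combinations (the null boundary $\delta = 0.05, \theta = -0.05$ and the
alternatives $\delta = 0.05, \theta = 0$ and $\delta = 0.10, \theta = 0$)
and four missingness settings (none, balanced 15%/15%, balanced 25%/25%,
arm-dependent 10%/30%) — 468 scenarios. Full runs use $10^4$ replicates
per scenario.

The package's own test suite runs scaled-down versions of these studies —
typically 2000 replicates per scenario and coarser $n$ grids — sized so that
each check's tolerance is at least three Monte-Carlo standard errors while
the whole suite finishes in minutes on one CPU. These scaled sizes are a
packaging choice to keep `R CMD check` fast; `scripts/acceptance.R`
re-runs the headline quantities at the full $10^4$-replicate protocol.

# Known limitations

* **Small-sample undercoverage of Wald-type intervals.** At $\theta = 0$
  with $n \lesssim 50$ and high within-pair correlation, the two-sided 90%
  MI and GEE intervals cover the true risk difference at roughly 87–88%
  rather than 90%. This is a genuine property of the Wald construction, not
  a numerical defect: exact enumeration of the complete-data Wald interval
  over the discordant-cell distribution gives true coverage of about 87.6%
  at $n = 20$, $\rho = 0.37$, and about 87.1–87.3% at $n = 30$–$50$,
  $\rho = 0.5$, in agreement with the package's Monte-Carlo estimates.
  Coverage recovers to the nominal level by $n \approx 200$. The score
  (Tango) interval does not share this defect.
* **GEE type-I error in very small samples.** With $n = 20$ clusters the
  sandwich covariance is noisy and the boundary rejection rate of the GEE
  method can exceed 15% under unbalanced MAR missingness. The delta-method
  standard error here uses the full coefficient covariance including the
  $\beta_0$–$\beta_1$ cross term; a variant that ignores the cross term
  gives smaller type-I error at the boundary but is not the correct
  first-order variance and is not implemented. At $\theta = 0$ the two
  variants coincide (the first gradient component vanishes), so interior
  coverage is unaffected. Use GEE for designs with at least ~100 clusters,
  or prefer the score test in small samples.
* **Missingness model.** All methods assume MAR at most; none address MNAR.
* The GEE implementation is specialized to the paired two-condition design
  (one binary covariate, clusters of size $\le 2$); it is not a
  general-purpose GEE solver.
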