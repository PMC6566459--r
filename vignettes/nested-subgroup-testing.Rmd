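---
title: "Multiplicity-adjusted testing of nested biomarker subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplicity-adjusted testing of nested biomarker subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestsub)
```

## The problem

A two-arm randomized trial measures a continuous baseline biomarker $X_i$
alongside the outcome $Y_i$. When it is plausible that the treatment helps
mainly patients with low biomarker values but the right cutoff is unknown,
a pre-specified ladder of thresholds $q_1 < \dots < q_K$ defines nested
biomarker-positive subpopulations $S^+(q_k) = \{i : x_i \le q_k\}$, and the
one-sided hypotheses

$$H_{0k}: \delta(q_k) \le 0 \quad \text{vs} \quad H_{1k}: \delta(q_k) > 0,
\qquad \delta(q_k) = \mu_t(q_k) - \mu_c(q_k)$$

are tested jointly. With $q_K$ at the top of the biomarker range the last
test is the ordinary full-population test. Because the subpopulations are
nested — each contains all smaller ones — the test statistics behave like
the interim statistics of a group-sequential trial: accumulating patients
play the role of accumulating information, and the correlation between the
statistics of subgroups $j \subset k$ is the information ratio
$\sqrt{I_j / I_k}$. Group-sequential critical boundaries (Pocock-type: one
common critical value; O'Brien–Fleming-type: stricter for smaller
subgroups) therefore suggest themselves.

The catch — and the reason this package exists — is a *prognostic* biomarker
effect that the test statistics do not model. Under the global null the
outcome can still depend on $X$; in a step-function dependence the full
population is then a two-component normal mixture while small subgroups are
homogeneous, so the outcome variance *grows* along the ladder. That distorts
the correlation structure away from $\sqrt{I_j/I_k}$, and boundaries
computed under the equal-variance assumption no longer control the
family-wise error rate (FWER). The package quantifies this by simulation
and provides procedures that stay valid.

## The data-generating model

`model_spec()` encodes
$$Y_i = \beta_0 + \beta_1 U_i + \beta_2 f(X_i) + \beta_3 U_i f(X_i) +
\varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$
with $U_i \in \{0, 1\}$ the arm indicator and $f$ a shape shared by the
prognostic ($\beta_2$) and predictive ($\beta_3$) components: a step at a
cutoff $\gamma$ (decreasing or increasing), a linear trend (decreasing or
increasing), or an indicator of the central band
$(0.5 - \gamma/2,\, 0.5 + \gamma/2]$. The central band is our reading of
"largest effects at intermediate biomarker values": among the admissible
shapes it is the one that keeps the prevalence of affected patients at
$\gamma$, which makes its operating characteristics directly comparable to
the step shapes. The two increasing shapes and the central band are
deliberate misspecifications of the `x <= q` subgroup direction, used to
probe robustness.

`simulate_trial()` draws exactly `n_per_group` subjects per arm (fixed
allocation — only the biomarker sampling makes subgroup sizes random, as in
a real trial), $X_i \sim U[0,1]$ independent of the arm, and normal errors.
What the generator does *not* emulate: non-uniform biomarker distributions,
non-normal or heteroscedastic errors within a subgroup, unequal
randomization, dropout, or measurement error in $X$. Passing tests
therefore certify the procedures under the stated sampling model, not under
arbitrary real-world violations; the misspecification shapes probe only the
direction and location of the biomarker effect.

## The six procedures

For data $d$ and a `nested_design(thresholds, alpha)`:

* **`sidak`** — pooled t statistics against per-subgroup t quantiles at
  level $1 - (1-\alpha)^{1/K}$. Valid under any positive dependence, but
  ignores the correlation, hence conservative (increasingly so for large
  $K$).
* **`z_gs`** — the "z-test": t statistics against the *normal-scale*
  Pocock boundary from the equal-variance covariance. Anti-conservative at
  small samples because the t scale is ignored.
* **`t_gs`** — the "t-test": the same boundary mapped to the t scale by
  quantile substitution $t_\alpha(q_k) = \Psi^{-1}_{df_k}(\Phi(c_\alpha))$,
  $df_k = n_t(q_k) + n_c(q_k) - 2$. Valid when variances are constant
  across subgroups; inflates the FWER under strong unadjusted prognostic
  effects.
* **`adjusted_t`** — the headline procedure: the covariance is estimated by
  plugging the realized subgroup variances into
  $\rho_{jk} = \frac{\sigma(q_j)}{\sigma(q_k)}
  \sqrt{\tfrac{1/n_t(q_k) + 1/n_c(q_k)}{1/n_t(q_j) + 1/n_c(q_j)}}$
  (pooled within-subgroup SDs; a general per-arm form is available via
  `covariance_form = "general"`), then Pocock root-finding and quantile
  substitution. Controls the FWER across all scenarios we simulate.
* **`regression`** — fits $Y = \beta_0' + \beta_1' U + \beta_2' X$ within
  each subgroup and tests $\beta_1'$ on $n_k - 3$ degrees of freedom, with
  the information $1/\widehat{Var}(\hat\beta_1')$ driving the covariance.
  Absorbs *linear* prognostic trends exactly; remains mildly
  anti-conservative when the true dependence is a step (model
  misspecification).
* **`inverse_normal`** — splits the population into the disjoint shells
  $(q_{k-1}, q_k]$, computes stage-wise t-test p-values and combines them:
  $C(q_k) = \sum_{m \le k} \sqrt{w_m}\,\Phi^{-1}(1 - p_m) \big/
  \sqrt{\sum_{j \le k} w_j}$, $w_m = [1/n_c + 1/n_t]^{-1}$ on shell $m$.
  Under the global null the shell p-values are independent and uniform, so
  the $C(q_k)$ are *exactly* standard normal with group-sequential
  correlation $\sqrt{I_j/I_k}$, $I_k = \sum_{m\le k} w_m$ — the boundaries
  apply on the normal scale with no quantile substitution, and FWER control
  needs no variance-homogeneity assumption at all. The price is a loss of
  degrees of freedom in small shells, visible as slightly lower power at
  $K = 8$.

All are single-step; strong FWER control follows from the closed testing
principle because each procedure's rejection region for a sub-family
contains the corresponding region for any super-family (asserted as a
property test on random datasets). `adjusted_pvalues()` inverts any of the
procedures by monotone bisection on $\alpha$ (tolerance `1e-8`), so
"adjusted $p \le \alpha$" and "rejected at level $\alpha$" agree by
construction.

General, non-nested subgroups (interval unions, e.g. the $2K-1$
tail-oriented STEPP sets from `stepp_tail_subgroups()`) are handled by
`run_general_procedure()`: the covariance uses the shared subjects of each
pairwise intersection, reduces algebraically to the nested formula for
nested sets, and is zero for disjoint sets. A user-supplied vector of
unequal critical values is accepted after validation against the
level-$\alpha$ condition.

## Numerical choices

**Orthant probabilities.** The level-$\alpha$ condition
$1 - \Phi_{0,\Sigma}(c, \dots, c) \le \alpha$ needs
$P(Z_1 \le c_1, \dots, Z_K \le c_K)$ repeatedly inside a root-finder, so
the integrator must be deterministic and fast. Every nested-design
covariance in this package (equal-variance, variance-adjusted simplified,
information-based) is *product-structured*, $\rho_{jk} = g_j / g_k$, which
makes $(Z_k)$ a Markov chain; we integrate by the classical
group-sequential recursion — propagate the truncated state density stage by
stage with Simpson quadrature on $[-8.5, c_k]$. With 201 grid points the
absolute error is below $10^{-6}$ (validated against high-precision
quasi-Monte-Carlo); the simulation fast path uses 61 points (error
$\approx 5\times10^{-6}$, i.e. $\approx 10^{-4}$ on the critical value,
far below Monte-Carlo noise). Non-product matrices — general subgroups, the
per-arm covariance form, and repaired matrices — fall back to Genz–Bretz
quasi-Monte-Carlo with a fixed internal seed (absolute tolerance
$10^{-6}$), so every boundary computation is reproducible. We abandoned a
third-party deterministic integrator after finding multi-$10^{-3}$,
non-monotone errors on realistic plug-in matrices.

**Root-finding.** The common critical value is bracketed between the
unadjusted quantile $\Phi^{-1}(1-\alpha)$ and the Bonferroni quantile
$\Phi^{-1}(1-\alpha/K)$ and solved to `1e-8`. The Monte-Carlo engine
instead runs a warm-started Newton iteration (a running slope estimate is
shared across replicates; $\approx 2$ integrand calls per solve) and caches
solutions keyed on the normalized $g$ vector rounded to 4 decimals — the
boundary depends on counts and variance estimates only through $g$, so the
key is exact for the problem actually solved.

**Plug-in covariances** can be marginally non-positive-semidefinite (or
have entries above 1) in finite samples; we clip negative eigenvalues at
zero, re-standardize the diagonal, and warn. Thresholds use inclusive
membership ($x \le q$); ties have probability zero under a continuous
biomarker.

**Degenerate subgroups** (an arm with fewer than 2 members, or zero pooled
variance) raise an instructive error in analysis mode; in simulation mode
the affected hypothesis counts as not rejected and the event is tallied —
a conservative rule for a case on which the methodology is silent.

**Randomness.** One root seed; replicate $r$ uses the derived substream
seed $(root + 1000003\,r) \bmod (2^{31}-1)$, so any replicate is
reproducible in isolation and results are independent of execution order.
Generators restore the caller's RNG state.

## Operating characteristics and sample size

`estimate_fwer()` (which refuses scenarios violating the global null),
`estimate_power()` (disjunctive power, always with the single
full-population t-test as comparator) and `scenario_grid()` reproduce the
simulation study design: $n = 80$ per group, $K \in \{2, 4, 8\}$
quantile-based thresholds $q_k = k/K$, step cutoffs
$\gamma \in \{0.2, 0.5, 0.8\}$, prognostic effects $\Delta \in [0, 3]$,
predictive effects up to 1 SD, $\sigma = 1$, one-sided $\alpha = 0.025$.
We default to $10^4$ replicates — the Monte-Carlo standard error of a
rate near 0.025 is then $\approx 0.0016$, sharp enough to resolve the
inflations of interest, and all paper-scale comparisons in the tests are
stated as multiples of the Monte-Carlo standard error. (The grids default
to steps of 0.5 in $\Delta$ and 0.25 in the effect size; both are
arguments.)

`analytic_two_sample_n()` inverts the noncentral-t power of the single
full-population test (df $2n-2$, noncentrality $d\sqrt{n/2}$); for a
standardized effect of 0.5 (0.2) at $\alpha = 0.025$ and power 0.9 it
returns 86 (527) per group. `sample_size_search()` does the same for the
multiple testing procedures by integer bisection over simulated power,
two-staged for speed: a coarse bisection at 1,000 replicates locates the
solution, then the full-replicate (default $10^4$) bisection runs on a
$\pm 6$ bracket around it, re-widening automatically if the pilot was off.
All candidate sizes share per-replicate substreams (common random numbers),
which keeps the estimated power curve monotone up to noise at the decision
boundary; because that boundary is where sampling noise bites, the returned
$n$ carries an inherent uncertainty of roughly $\pm 2$ subjects at these
replicate counts. Under the step model with a 1-SD effect confined to the
biomarker-positive half ($\gamma = 0.5$) the adjusted t-test with $K = 4$
reaches 90% disjunctive power near $n = 54$ per group, against 86 for the
single full-population test of the diluted 0.5-SD effect; for
$\gamma = 0.2$ the contrast is $\approx 180$ versus 527.

## Known limitations

Continuous outcomes with a single biomarker only; pooled-variance (not
Welch) t statistics, matching the boundary theory's within-subgroup
homogeneity assumption; single-step decisions (a sequentially rejective
closed-test refinement would add power for secondary rejections but not
change the disjunctive rate); Pocock and O'Brien–Fleming boundary families
only; the Monte-Carlo engine supports the common-boundary (Pocock) family.
Analytic power for the multiple procedures is not available in closed form
— sample sizes come from simulation, with the $\pm 2$-subject caveat above.
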