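---
title: "Sample size determination with commensurate predictive priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size determination with commensurate predictive priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssd)
```

## The problem

A new two-group experiment (the motivating case is a rare-disease trial
comparing a new treatment against standard of care) is to be sized under a
fully Bayesian analysis, and relevant pre-experimental information exists in
several places at once: historical studies, registries, elicited expert
opinion. Each source $k = 1, \dots, K$ has been reduced to a normal summary
$\theta_k \mid y_k \sim N(m_k, s_k^2)$ of the source-specific analogue of the
new experiment's effect $\mu_\Delta$ (a difference in means, or a log-odds
ratio via `logodds_summary()`). Trusting any single source fully is fragile;
ignoring them all wastes exactly the information that makes a small trial
viable. `cssd` synthesises the sources into one *robust collective prior*
and solves for the sample size that delivers a requested average property of
the posterior.

## The collective prior

Each source is linked to the new experiment through a commensurate
predictive distribution $\tilde\theta_k \mid \theta_k, \nu_k \sim
N(\theta_k, \nu_k^{-1})$, where the precision $\nu_k$ measures how
commensurate the two parameters are. The prior on $\nu_k$ is a
two-component Gamma mixture,

$$\nu_k \sim w_k\,\mathrm{Gamma}(a_{01}, b_{01}) +
  (1 - w_k)\,\mathrm{Gamma}(a_{02}, b_{02}),$$

with **shape–rate** parameterisation throughout, so the predictive-variance
contribution of component $j$ is $E[1/\nu] = b_{0j}/(a_{0j}-1)$. The first
component sits on small precisions (down-weighting), the second on large
ones (strong borrowing); the elicited weight $w_k \in [0,1]$ is the prior
probability of *in*commensurability. Marginalising $\nu_k$ gives a
two-component mixture of nonstandardised t distributions
(`t_mixture_pdf()`, component $j$ with $2a_{0j}$ degrees of freedom and
scale $\sqrt{b_{0j}/a_{0j}}$), which is moment-matched by a normal with
variance $w_k b_{01}/(a_{01}-1) + (1-w_k) b_{02}/(a_{02}-1)$
(`moment_match_variance()`; it requires $a_{01}, a_{02} > 1$). The package
tests verify the match against quadrature of the t-mixture density at
relative tolerance $10^{-6}$.

The sources are combined as $\mu_\Delta = \sum_k p_k \tilde\theta_k$ with
synthesis weights

$$p_k = \frac{\exp(-w_k^2 / s_0)}{\sum_j \exp(-w_j^2 / s_0)},$$

yielding the collective prior
$\mu_\Delta \sim N\!\big(\textstyle\sum_k p_k m_k,\; \sum_k p_k^2 \xi_k^2\big)$
with $\xi_k^2 = s_k^2 + w_k b_{01}/(a_{01}-1) + (1-w_k) b_{02}/(a_{02}-1)$
(`collective_prior()`). Note $\xi_k^2 \ge s_k^2$ always: borrowing never
claims more precision than the source itself reported.

### Tunable parameters

* **Mixture components** — default $\mathrm{Gamma}(2,2)$ (predictive
  variance 2, on the effect scale squared) and $\mathrm{Gamma}(18,3)$
  (predictive variance $3/17$). They encode the two extremes reached at
  $w_k = 1$ (very limited borrowing) and $w_k = 0$ (near-pooling). The
  constructor rejects component pairs whose predictive variances are
  ordered the wrong way round, because a silent swap re-scales every
  collective variance. Sensitivity: strengthening the borrowing component
  (e.g. $\mathrm{Gamma}(54,3)$) moves sample sizes much less than weakening
  it (e.g. $\mathrm{Gamma}(6,3)$) — diminishing returns that the test suite
  checks.
* **Concentration $s_0$** (default 0.05, dimensionless) — how sharply the
  synthesis weights discriminate among the $w_k$. $s_0 \gg \max w_k$ gives
  $p_k \to 1/K$; $s_0 \to 0^+$ concentrates on the smallest $w_k$ (exact
  ties split equally, by symmetry). Small values relative to the spread of
  the $w_k$ are recommended so the degree of relevance is actually
  discerned.
* **Weights $w_k$** — user input. `hellinger_normal()` (closed form,
  verified against quadrature) helps judge pairwise discrepancy among the
  $N(m_k, s_k^2)$ when eliciting them, but no automatic distance-to-weight
  mapping is imposed: that mapping is a substantive elicitation choice, not
  a numerical one.

## Variance models

The sampling variance $\sigma_0^2$ of the new experiment is either known,
or unknown with the chi-square link
$c\,S/\sigma_0^2 \sim \chi^2(c)$, where $S = \sum_k p_k^2 \xi_k^2$ —
equivalently $\sigma_0^2 \sim \text{Inv-Gamma}(c/2,\, cS/2)$
(**shape–scale**: density $\propto x^{-\alpha-1} e^{-\beta/x}$). The prior
degrees of freedom $c$ set how strongly the historical basis informs the
variance; $c \to \infty$ recovers the known-variance model at
$\sigma_0^2 = S$, which is also the "optimal" benchmark strategy. The
prior mean $E[\sigma_0^2] = cS/(c-2)$ exists only for $c > 2$, so the
closed-form ACC/APVC solutions refuse $c \le 2$; the ALC solver does not
need the mean and works for every $c > 0$.

## The three criteria

Writing $Q = n_A n_B / (n_A + n_B)$ for the harmonic-mean information level
and $\sigma_N^2 = (1/S + 1/((1/n_A + 1/n_B)\sigma_0^2))^{-1}$ for the
conjugate posterior variance:

* **ACC** (`acc_criterion(l0, alpha)`): the HPD interval of fixed length
  $\ell_0$, centred at the posterior mean, has average coverage at least
  $1-\alpha$. Closed form:
  $Q \ge (4 z_{\alpha/2}^2/\ell_0^2 - 1/S)\,E[\sigma_0^2]$.
* **ALC** (`alc_criterion(l, alpha0)`): the $(1-\alpha_0)$-coverage HPD
  interval has average length $2 z_{\alpha_0/2} E[\sigma_N] \le \ell$. With
  known variance the length is deterministic and ALC coincides with ACC;
  with unknown variance $E[\sigma_N]$ has no closed form and the smallest
  integer total is found by search.
* **APVC** (`apvc_criterion(eps0)`): average posterior variance at most
  $\varepsilon_0$; closed form $Q \ge (1/\varepsilon_0 - 1/S)\,E[\sigma_0^2]$.

A negative right-hand side is clamped to $Q = 0$: the prior alone already
meets the target. Closed-form criteria report the *continuous* total
$Q(1+r)^2/r$ for allocation ratio $r = n_A/n_B$ (so equal allocation gives
$4Q$, and totals like 41.8 are meaningful); the ALC search reports the
smallest integer total, allowing fractional per-arm sizes under equal
allocation (odd totals are legitimate), with an opt-in `even_total` policy.

### Numerical choices

* $E[\sigma_N]$ is integrated on the precision scale
  ($\tau = 1/\sigma_0^2 \sim \mathrm{Gamma}(c/2, \text{rate } cS/2)$) with
  adaptive quadrature at relative tolerance $10^{-8}$, between the
  $10^{-13}$ and $1-10^{-13}$ gamma quantiles: the integrand is bounded by
  $\sqrt{S}$, so the truncated mass is negligible while finite limits keep
  the quadrature reliable when the density is sharply peaked at large $c$.
* The ALC search brackets exponentially from $n = 1$, bisects on the
  monotone expected-length function, then scans downward one step at a
  time to guarantee minimality.
* The unknown-variance posterior is handled by conditioning on
  $\sigma_0^2$ (where it reduces exactly to the known-variance conjugate
  update) and integrating at the criterion level; the normal-times-t
  marginal kernel is exercised only by a test that checks proportionality
  of log-densities on a grid.
* Display rounding is one decimal (round-half-even); serialised output
  keeps full precision.

## Comparator strategies

`ssd_design()` accepts `strategy =` `"robust"` (the elicited $w_k$),
`"no_robustification"` (all $w_k = 0$), `"no_borrowing"` (all $w_k = 1$;
the collective variance so obtained may still inform an unknown
$\sigma_0^2$ through the chi-square link — borrowing through the variance
is distinct from borrowing through the effect), `"single_source"` (the
smallest-variance $N(m_k, s_k^2)$ used directly; ties broken by lowest
index), and `"optimal"` (the robust prior with $\sigma_0^2$ known and
equal to $S$ — the perfect-commensurability benchmark). For every scenario
and criterion, robust totals are bracketed by no-robustification below and
no-borrowing above; the tests assert this across the whole benchmark grid.

## Worked example

```{r}
app <- application_scenario()
prior <- collective_prior(app$sources)
prior
ssd_design(app, acc_criterion(l0 = 0.65, alpha = 0.05),
           variance = list(kind = "known", sigma02 = 0.35))
ssd_design(app, alc_criterion(l = 0.65, alpha0 = 0.05),
           variance = list(kind = "invgamma", c = 5))
```

## What the Monte-Carlo verification does (and does not) show

`mc_average_properties()` replays a design forward: draw $\sigma_0^2$ from
the variance model, draw the realised difference in sample means from the
marginal predictive law
$N(\sum_k p_k m_k,\, (1/n_A + 1/n_B)\sigma_0^2 + S)$, form the conjugate
posterior, and average HPD coverage, credible length, and posterior
variance (default $10^5$ replicates, seeded, seed recorded in the output).
This emulates exactly the probability space the criteria average over — a
normal effect drawn from the collective prior and normal data — so passing
checks certify the *internal* consistency of the formulas, not robustness
to non-normal outcomes, prior–data conflict, or misspecified $w_k$, none
of which the generator produces. Two structural facts are worth knowing:

* With known variance, coverage of the centred fixed-length interval and
  the credible length are data-free, so their simulation variance is zero
  and the ACC/APVC equalities at the solved $n$ are exact.
* With unknown variance, the closed-form ACC/APVC substitute
  $E[\sigma_0^2]$ into the bound; by Jensen's inequality the realised
  averages then over-deliver slightly (e.g. average coverage ≈ 0.955 at a
  nominal 0.95 for $c = 5$). The criteria are met conservatively; the
  tests assert bound satisfaction, and equality only where it is exact.

## Problem sizes and defaults used in the shipped checks

The test-suite and acceptance computations run on the five-source worked
application and the eight five-source benchmark configurations — the scale
this methodology is designed for (desk-scale: every closed form is
instantaneous, an ALC search takes a handful of quadratures). Monte-Carlo
checks use $10^5$ replicates, which puts three standard errors around
$2\times10^{-3}$ on a coverage probability — tight enough to detect a
formula defect while keeping the full suite in seconds.

## Known limitations

* Normal approximations are used twice (t-mixture moment match; collective
  convolution); their quality degrades for very heavy-tailed components
  (small $a_{0j}$) or strongly divergent sources.
* A common $\sigma_0^2$ across arms is assumed; unequal per-arm variances,
  interim re-estimation of $w_k$, time-to-event outcomes, and
  hypothesis-testing (type-I-error calibrated) sizing are out of scope.
* An unknown-variance design can need *fewer* participants than its
  known-variance counterpart whenever the chi-square link centres
  $\sigma_0^2$ on a collective prior variance smaller than the fixed value
  assumed in the known case (in the worked example, $S \approx 0.154$
  versus $\sigma_0^2 = 0.35$). This is a feature of informing the variance
  from the historical basis, not a bug — but it means known- and
  unknown-variance totals are only comparable jointly with their variance
  assumptions.
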