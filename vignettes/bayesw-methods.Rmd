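---
title: "Methods: Bayesian spike-and-slab Weibull regression for age-at-onset phenotypes"
author: "bayesw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian spike-and-slab Weibull regression for age-at-onset phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bayesw` fits a whole-genome accelerated failure time model to a censored,
optionally left-truncated age-at-onset phenotype. Event times are Weibull;
equivalently the log time is Gumbel with

$$E(\log Y_i) = \mu + \mathbf{x}_i'\boldsymbol\beta + \mathbf{z}_i'\boldsymbol\delta,
\qquad \mathrm{Var}(\log Y_i) = \frac{\pi^2}{6\alpha^2},$$

where $\mathbf{x}_i$ are standardised SNP allele counts, $\mathbf{z}_i$
fixed covariates, and $\alpha$ the Weibull shape. This parametrisation
separates location (genetics, covariates) from residual spread (shape), so a
log-scale SNP heritability is well defined. The likelihood handles right
censoring exactly and left truncation by conditioning on survival to the
entry age; a zero entry age contributes no truncation term.

Marker effects carry a grouped Dirac spike-and-slab mixture prior,

$$\beta_j \sim \pi_0^{\varphi}\,\delta_0 + \sum_{k=1}^{L_\varphi}
\pi_k^{\varphi}\, N(0,\, C^\varphi_k \sigma^2_{G\varphi}),$$

with disjoint marker groups $\varphi$ (e.g. MAF-by-LD bins), group-specific
mixture proportions $\boldsymbol\pi^\varphi$ and genetic variances
$\sigma^2_{G\varphi}$; the slab constants $C_k$ encode the magnitude of
per-marker variance each component captures. The total genetic variance is
the sum of the group variances.

## The sampler

Conjugate updates exist for $\boldsymbol\pi$ (Dirichlet with occupancy
counts) and $\sigma^2_{G\varphi}$ (inverse gamma). The conditionals of
$\mu$, $\alpha$, $\delta_q$ and the non-zero $\beta_j$ are log-concave but
non-standard; they are drawn with *derivative-free adaptive rejection
sampling*: secants of the log-density form a squeeze, their extensions an
upper hull, and rejected proposals refine the envelope. The envelope masses
and inverse-CDF draws are computed in log space, so arbitrarily steep hull
segments cannot overflow.

Mixture membership $\gamma_j$ requires the marginal likelihood of each
component with $\beta_j$ integrated out. After reparametrising by
$s = \beta_j/\sqrt{2C_k\sigma^2_G}$ the integral is evaluated by adaptive
Gauss–Hermite quadrature with the expansion point fixed at zero (effects are
symmetric about zero) and scale
$\hat\sigma_k = 1/\sqrt{2(1+\alpha^2C_k\sigma^2_G\sum_i x_{ij}^2 w_i)}$,
where $w_i = e^{v_i} - e^{u_i}$ are the event/truncation residual
exponentials. Because the integrand carries its own Gaussian factor, the
quadrature uses the modified weights $w_r e^{t_r^2}$; with them the identity
$\int e^{-s^2} ds = \sqrt\pi$ is exact for any number of nodes, which the
tests assert. All marginals are normalised by the shared factor
$T=\exp\{\sum_i(e^{u_i}-e^{v_i})\}$, on which scale the Dirac spike marginal
is exactly $\sqrt\pi$; membership probabilities are a max-shifted softmax
over log marginals and therefore never produce `NaN` under underflow.

Per-marker work uses the three-valued genotype coding: the quadrature data
terms and the residual updates reduce to the class sums $V_0, V_1, V_2$ of
$w_i$ over 0/1/2 carriers, so one marker update costs O(#carriers) rather
than O(N). Missing genotypes are mean-imputed (standardised value exactly
zero), never enter a carrier set, and the non-missing class total is used
where the algebra requires it. Sparse and dense forms are asserted equal to
1e-10 in the tests.

### Bulk-synchronous-parallel variant

`gibbs_bsp()` partitions markers into contiguous blocks held by logical
workers. Within a synchronisation window each worker processes `sync_rate`
of its markers against the window-start residual state, accumulating a
residual message; at the barrier all messages are applied and the
exponentiated residuals refreshed. With one worker and a window of one
marker the algorithm *is* the serial sampler — the two drivers share one
engine, so that reduction is exact by construction. Workers are logical
(single process): the contract, not multi-node transport, is what is
implemented here.

## Numerical choices

* Hard sampling limits: $\mu \in (2, 5)$ on the log-time scale, $\alpha \in
  (0, 40)$, covariate effects at prior mean $\pm 10$ prior SD. A marker
  effect is sampled within its previous value $\pm 2\sqrt{C_k\sigma^2_G}$ —
  the interval that adapts to the mixture and is meant to retain essentially
  all conditional mass. Early in a chain $\sigma^2_G$ is initialised at
  $\mathrm{Var}(\log y)/M$, which is tiny for genome-sized $M$; a strongly
  supported effect then lies far outside that default interval and the
  chain would need hundreds of iterations of micro-steps to inflate the
  genetic variance. The implementation therefore widens the interval
  geometrically while the conditional log-density at an edge is within 9
  nats of its value at the previous effect (roughly $\pm 4.2$ slab SD for a
  Gaussian), which restores the interval's stated purpose; the default rule
  is unchanged whenever the mass check passes.
* ARS initial abscissae: $\{\hat\theta - c, \hat\theta, \hat\theta + c\}$
  around the previous value, with $c = 0.5$ for $\mu$, $\alpha$, $\delta_q$
  and $c = \sqrt{C_k\sigma^2_G}$ for $\beta_j$.
* Exponent arguments are capped at 700 before exponentiation (with a
  warning), so a wild early iteration cannot overflow the residual state.
* The Euler–Mascheroni constant is computed as $-\psi(1)$, not transcribed.
* Hermite nodes/weights are computed once per node count and cached;
  default 25 nodes (membership probabilities change by $<10^{-4}$ between 7
  and 25 nodes on Weibull-simulated data).
* $\sigma^2_{G\varphi}$ conditional: shape $\alpha_\sigma + m_\varphi/2$ and
  scale $\beta_\sigma + \tfrac12\sum_j \beta_j^2/C_{\gamma_j}$, the
  conjugate update for the stated prior, validated by a successive-
  conditional (Geweke-style) test in the suite.
* Mixture indicator draws use inverse-CDF on a single uniform with
  component order (spike, ascending $C_k$); marker visit order is a fresh
  uniform shuffle each iteration (within each worker's block under BSP).
* Initial state: everything out of the model, $\mu = \overline{\log y}$,
  $\alpha = \sqrt{\pi^2/(6\widehat{\mathrm{Var}}(\log y))}$ (the inversion
  of the Gumbel variance identity), $\sigma^2_G = \widehat{\mathrm{Var}}
  (\log y)/M$ split equally across groups, and $\pi^\varphi_0 = 0.99$ with
  the slab mass split equally (the initial proportions are not critical:
  they are resampled from occupancy counts after one sweep).

## Heritability estimator

The log-scale SNP heritability of draw $t$ is
$h^2_t = V_{G,t}/(V_{G,t} + \pi^2/(6\alpha_t^2))$. Two choices of $V_{G,t}$
are offered. The default, `genetic_variance = "realized"`, uses the variance
over individuals of $X\beta_t$. The alternative, `"hyper"`, uses the sampled
hyperparameter $\sum_\varphi \sigma^2_{G\varphi}$ — the textbook reading of
the formula. The default is the realized variance because the
hyperparameter is consistent with the realized genetic variance only when
the slab grid brackets the causal markers' per-marker variance share
($\approx 1/p$ of the genetic variance): with the conjugate update the
posterior mean of $\sigma^2_G$ is approximately
$\sum_j \beta_j^2 / (C_{\gamma_j}\, m)$, so when true effects are larger
than the top slab accommodates (as in a sparse architecture analysed with a
modest grid) the hyperparameter inflates by the ratio of the causal share
to $C_{\max}$ while $\mathrm{Var}(X\beta)$ stays calibrated. The realized
estimator is also invariant to the placement of the grid. Both are stored
on every fit.

## The synthetic-data generator

`simulate_survival_study()` emulates the study conditions the model
targets: unlinked binomial genotypes with allele frequencies uniform on
(0.05, 0.5); `p_causal` effects drawn $N(0, \sigma^2_G/p)$ at random
markers; log time $= \mu_0 + g_i + e_i$ with $e_i$ a *standardised* log
generalised-gamma draw of index $\theta$ ($\theta = 1$: Gumbel error, i.e.
Weibull times; $\theta = 0$: Gaussian error, i.e. log-normal times; the
standardisation uses closed-form digamma/trigamma moments, not empirical
ones), scaled to $\mathrm{Var}(g)(1-h^2)/h^2$ so the log-scale heritability
is fixed at `h2`. Defaults chosen once for realism: $\mu_0 = 3.6$ log-years
(an onset scale of about 37 years, inside the sampler's intercept limits)
and an error scale matching a true Weibull shape of 4 — values typical of
adult-onset disease phenotypes. Right censoring picks a uniform random
subset of individuals of exactly the requested fraction and replaces each
time with a uniform draw on $(0, y_i)$; the mechanism is isolated in
`apply_censoring()` so an alternative censoring-time law can be swapped in.
Because the censoring time depends on the event time, the mechanism is
mildly informative: at 40% censoring the posterior-mean heritability shifts
upward by a few hundredths on otherwise identical data, which the
censoring-level test accounts for by asserting recovery of the generative
value rather than exact invariance.

What the generator does *not* emulate: linkage disequilibrium (markers are
independent; `ld_clump()` on such data yields near-singleton clumps),
population structure and relatedness, MAF-dependent architecture, dosage
uncertainty, or informative censoring. Passing tests on these simulations
therefore demonstrates correctness of the algorithmic machinery and
calibration under the assumed generative family, not robustness to the
full complexity of biobank data.

## Problem sizes used in the checks

The end-to-end suite fits: one study of $N = 2000$, $M = 5000$, 50 causal
markers (heritability recovery, effect-size slope, hold-out prediction);
five replicates of $N = 1200$, $M = 1500$, 20 causal (region-level FDR at
PPWV $\ge 0.9$, threshold 1/1000 of the genetic variance, matching the
magnitude of the smallest slab constant in the two-component grid used);
$N = 800$, $M = 1000$ for serial/BSP agreement; and $N = 1000$, $M = 1000$
for posterior predictive coverage. These sizes were chosen as the smallest
at which the corresponding scientific property is expected to hold with
comfortable Monte Carlo margins.

## Known limitations

* No proportional-hazards estimation, time-varying covariates or competing
  risks; the model is a parametric AFT throughout.
* The intercept limits (2, 5) assume time units in which log onset ages
  fall in that range (e.g. years for adult-onset traits); rescale the time
  unit otherwise — the fit warns when the mean log time falls outside.
* The BSP variant trades per-window residual staleness for parallelism;
  with aggressive `workers * sync_rate` relative to the marker count and
  strong LD the window-start approximation degrades (on unlinked
  simulations posterior means agree with the serial sampler within Monte
  Carlo error, which is what the suite asserts).
* The `"hyper"` heritability estimator inherits the grid-dependence
  discussed above; reports should use the default unless the grid is known
  to bracket the architecture.
* When the marker count is comparable to the sample size and the phenotype
  carries little or no genetic signal, the flat Dirichlet prior on the
  mixture proportions leaves them weakly identified: the posterior keeps
  diffuse mass on many tiny "phantom" effects. Region-level PPWV
  discoveries remain clean (none reach the 0.9 criterion on null
  simulations) and the `"hyper"` heritability stays near zero, but raw
  single-marker PIPs are not null-calibrated and the realized-variance
  heritability absorbs the overfitting mass (about 0.1 on null simulations
  with $M = N = 1000$). Use PPWV for discovery and interpret the realized
  heritability when signal dominates; under strong signal the inflated
  genetic variance penalises phantom inclusion and the effect disappears.
* PPWV uses the per-draw total genetic variance as its denominator
  (self-consistent across draws); a posterior-mean denominator is a
  near-identical alternative for well-mixed chains.
* Whether the A1 or the minor allele is counted is irrelevant to the fit
  (the model is sign-symmetric after standardisation) but matters when
  transporting effect estimates; `read_plink()` counts A1.
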