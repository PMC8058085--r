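# bayesw

Whole-genome Bayesian analysis of **censored age-at-onset phenotypes** under
a Weibull accelerated failure time model with a grouped spike-and-slab
mixture prior on marker effects.

Genome-wide association studies usually analyse age-at-onset traits (age at
menopause or menarche, age at diagnosis of hypertension, diabetes, coronary
artery disease, ...) as binary case/control outcomes, discarding both the
timing information and the censored individuals who had no event by their
last visit. `bayesw` is for statistical geneticists who want to model the
time dimension directly at biobank-style marker counts: it jointly estimates
all marker effects, the trait's genetic architecture, and a genomic
predictor with calibrated posterior predictive intervals, while handling
right censoring (and optional left truncation) exactly.

## Model

The event time of individual *i* is Weibull, so its log is Gumbel with

    E(log Y_i)   = mu + x_i' beta + z_i' delta
    Var(log Y_i) = pi^2 / (6 alpha^2)

where `x_i` are standardised allele counts, `z_i` covariates and `alpha`
the Weibull shape: location carries the genetics, the shape carries the
residual spread, and `h2 = V_G / (V_G + pi^2/(6 alpha^2))` is the log-scale
SNP heritability. Marker effects have a Dirac spike-and-slab mixture prior,
per marker group `phi` (e.g. MAF-by-LD bins):

    beta_j ~ pi_0 delta_0 + sum_k pi_k N(0, C_k sigma2_G(phi))

The Gibbs sampler uses derivative-free **adaptive rejection sampling** for
the log-concave conditionals of `mu`, `alpha`, `delta`, `beta_j`, adaptive
**Gauss–Hermite quadrature** for the spike/slab marginal likelihoods (the
Dirac-spike marginal has a closed form), and **sparse partial-sum algebra**
over the three genotype classes so one marker update costs O(#carriers). A
bulk-synchronous-parallel variant (`gibbs_bsp()`) processes marker blocks
against window-start residuals and reduces exactly to the serial sampler at
one worker and window size one. Post-processing covers heritability,
LD-clump-based **PPWV** (posterior probability of window variance) region
significance, genomic prediction with posterior predictive intervals,
precision–recall / FDR-vs-PIP, Harrell's C and martingale residuals.

## Worked example

Simulate a Weibull (theta = 1) study — 1000 individuals, 2000 unlinked
markers, 20 causal, log-scale heritability 0.5, 20% censoring — and fit it:

```r
library(bayesw)
set.seed(42)
sim <- simulate_survival_study(n = 1000, m = 2000, p_causal = 20, h2 = 0.5,
                               theta = 1, censoring = 0.2)
df  <- data.frame(time = sim$data$time, status = sim$data$failure)
fit <- bayesw(survival::Surv(time, status) ~ 1, df, sim$genotypes,
              mixtures = c(0.001, 0.01), iterations = 1500, burnin = 750,
              thinning = 5, seed = 1)
fit
#> Bayesian spike-and-slab Weibull regression
#>   1000 individuals (800 events), 2000 markers, 1 chain(s) x 150 draws
#>   posterior mean shape 2.965, intercept 3.635, h2 0.525
#>   markers in model (posterior mean): 21.5
heritability(fit)
#> Log-scale SNP heritability (realized): 0.525 [0.483, 0.564] (95% CI)
```

The generative heritability (0.5) is recovered, and the posterior keeps
about 21 markers in the model (20 are causal). Region-level discoveries use
PPWV — the posterior probability that an LD clump explains at least a given
share of the genetic variance:

```r
regions <- ld_clump(sim$genotypes, rank = pip(fit))
tab  <- ppwv(fit, regions, thresholds = 1e-3)
disc <- tab$region[tab$ppwv >= 0.9]
length(disc)                                   # 13 regions declared
#> [1] 13
sum(sapply(disc, function(r) any(regions[[r]] %in% sim$truth$causal)))
#> [1] 13                                       # ... all of them true
harrell_c(predict(fit), sim$data$time, sim$data$failure)
#> [1] 0.781
```

All 13 regions passing `PPWV >= 0.9` contain a true causal marker (the
remaining causal effects are too small to declare), and the genomic
predictor reaches a concordance of 0.78 on the training cohort.
`predict(fit, new_genotypes)` ports the predictor to an independent cohort;
`predict(fit, type = "interval")` returns 95% posterior predictive time
intervals.

A thin command-line wrapper (`inst/cli/bayesw`) exposes
`simulate / fit / predict / ppwv / metrics` subcommands over PLINK 1
bed/bim/fam files and writes a JSON manifest per run.

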