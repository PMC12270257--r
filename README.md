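# pedpen

Bayesian estimation of age-specific, sex-specific **penetrance** — the
probability that a carrier of a pathogenic germline variant develops a
disease by a given age — from family-history pedigree data. The package is
aimed at genetic epidemiologists and statisticians working with
family-based studies (e.g. cancer-syndrome registries) in which a proband
is genotyped, relatives usually are not, and disease status is observed up
to each individual's censoring age.

## Model

Carrier onset follows a modified Weibull cumulative distribution

F(t | α, β, γ, δ) = γ · (1 − exp(−((t − δ)/α)^β)),  t > δ,

with scale α > 0 and shape β > 0, an **asymptote** γ ∈ (0, 1) (lifetime
risk among carriers) and a **threshold** δ ≥ 0 (minimum onset age).
Noncarrier risk is approximated by a registry-style baseline cumulative
risk table (carriers being rare). For a single biallelic autosomal locus
with founder genotypes in Hardy–Weinberg equilibrium at the supplied
carrier prevalence, each family's likelihood marginalizes the unobserved
genotypes by **Elston–Stewart peeling** (implemented as sum–product
variable elimination in C++; exactness is cross-checked against explicit
3ⁿ enumeration). Estimation runs in the quantile-space parameterization
(q1, med, γ, δ) — the first-quartile and median onset ages among
eventually-affected carriers — with priors

- q1: scaled Beta(6, 3), med: scaled Beta(2, 2) (sequential interval
  scaling δ → q1 → med, so δ < q1 < med always holds),
- γ: Beta(1, 1), δ: Uniform(5, 30) years,

explored by an adaptive Metropolis random walk (proposal covariance
2.38²/d · (Σ̂ + εI), out-of-bounds proposals rejected outright). Priors can
also be elicited from published relative risks or Kaplan–Meier-style
age-specific risk points. Missing onset/censoring ages can be imputed
in-chain from the carrier-posterior-weighted onset mixture.

## Worked example

```r
library(pedpen)
peds     <- read_pedigrees(system.file("extdata", "example_pedigrees.csv", package = "pedpen"))
baseline <- read_baseline(system.file("extdata", "example_baseline.csv", package = "pedpen"))
validate_pedigree(peds)
#> validation_report: 0 error(s), 0 warning(s); 3 families, 125 individuals,
#>   14 affected, 3 carriers observed

cfg <- mcmc_config(n_chains = 2, n_iter = 2000, seed = 1, sex_specific = FALSE)
fit <- estimate_penetrance(peds, prevalence = 0.01, baseline = baseline, cfg = cfg)
#> posterior_samples: 2 chain(s) x 2000 iterations (200 burn-in discarded per chain)
#> acceptance rates: 0.263, 0.267

summ <- summarize_posterior(fit)
summ$curves$all[c(50, 70), c("age", "mean", "lower_0.95", "upper_0.95")]
#>    age      mean lower_0.95 upper_0.95
#> 50  50 0.2142064  0.1067854  0.3477062
#> 70  70 0.4337788  0.2565058  0.6196779

mcmc_diagnostics(fit)
#> mcmc_diagnostics:
#>  parameter   ess   rhat
#>         q1 172.3 1.0008
#>        med 173.9 1.0057
#>      gamma 214.1 1.0025
#>      delta 150.2 1.0238
```

The two printed curve rows say: a carrier of this (simulated) variant has
an estimated 21% probability of disease by age 50 (95% credible interval
11–35%) and 43% by age 70 (26–62%). The short demonstration chains above
are for illustration; defaults are 4 chains of 20,000 iterations with 10%
burn-in.

A simulator with known ground truth generates complete synthetic family
studies (three-generation structures around a carrier proband, mean family
size ≈ 35):

```r
study <- simulate_study(sim_design(n_probands = 130, seed = 1))
pedigree_summary(study$peds)
```

## Command line

```sh
Rscript -e 'pedpen::penetrance_cli()' simulate --families 50 --prev 0.0005 --out sim
Rscript -e 'pedpen::penetrance_cli()' estimate --pedigree sim/pedigrees.csv \
    --baseline baseline.csv --prev 0.0005 --iters 20000 --burn-in 0.1 --out fit
```

Exit codes: 0 success, 1 usage error, 2 validation failure, 3 runtime
failure.

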