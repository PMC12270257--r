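---
title: "Methods: Bayesian penetrance estimation from pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian penetrance estimation from pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

A family-based study ascertains families through a proband who carries a
pathogenic germline variant. The proband is typically the only genotyped
member; relatives contribute disease status (affected at a diagnosis age,
or unaffected up to a censoring age) and their position in the pedigree.
The quantity of interest is the carrier penetrance function: the
probability that a carrier develops the disease by each age, possibly
separately by sex.

## Onset model and its assumptions

Carrier onset follows a modified Weibull CDF
$F(t) = \gamma\,(1 - e^{-((t-\delta)/\alpha)^\beta})$ for $t > \delta$
and $0$ otherwise. The asymptote $\gamma \in (0,1)$ is the lifetime risk
among carriers; the threshold $\delta \ge 0$ is the minimum onset age.
Assumptions worth stating explicitly:

- **Single disease, no competing risks.** An affected individual
  contributes the annual onset probability at the diagnosis age; nothing
  after diagnosis is modelled. Censoring (death or end of follow-up) is
  assumed independent of onset.
- **Dominant collapse.** Heterozygous and homozygous carriers share one
  penetrance curve; homozygotes remain a distinct state only for correct
  Mendelian transmission.
- **Noncarrier risk = population risk.** Carriers are rare, so a
  registry-style age-specific cumulative risk table stands in for the
  noncarrier penetrance.
- **Unimodal parametric shape.** A single modified Weibull cannot express
  bimodal or plateau-then-rise onset patterns.

The model is discretized by annual differencing onto integer ages
$1..max\_age$ (default 94), matching annual registry tables; fractional
input ages are rejected rather than rounded. Coarse baseline tables are
linearly interpolated (anchored at zero risk at age 0, constant beyond the
last supplied age) before differencing.

## Quantile-space parameterization and priors

Estimation runs on $(q_1, med, \gamma, \delta)$, where $q_1$ and $med$
are the ages by which a quarter and half of eventually-affected carriers
have onset. The closed-form map to $(\alpha, \beta)$ is
$\beta = \log(\log(4/3)/\log 2)\,/\,\log((q_1-\delta)/(med-\delta))$,
$\alpha = (med-\delta)/(\log 2)^{1/\beta}$; spacings below $10^{-6}$
years are rejected as degenerate ($\beta \to \infty$).

Default priors are: first quartile scaled Beta(6, 3); median scaled
Beta(2, 2); asymptote Beta(1, 1); threshold Uniform(5, 30) years. The
published shapes do not state the scaling intervals, so this package uses
**sequential scaling**: $\delta \sim U(5, 30)$;
$q_1 = \delta + B_1 (max\_age - \delta)$ with $B_1 \sim$ Beta(6, 3);
$med = q_1 + B_2 (max\_age - q_1)$ with $B_2 \sim$ Beta(2, 2). This makes
the ordering $\delta < q_1 < med < max\_age$ hold with prior probability
one — no rejection steps, and the quantile-to-Weibull map never sees
invalid input. The log-density includes the interval-scaling Jacobians;
a quadrature test verifies it integrates to one. The practical
consequence worth knowing: the implied prior mean of the median onset age
is roughly $(q_1 + max\_age)/2 \approx 70$ years, which matters when the
data end early (see *Limitations*).

Although the threshold is described as strictly positive, the
implementation accepts $\delta = 0$; the default prior support
$[5, 30]$ enforces positivity in practice.

### Prior elicitation from published summaries

- **Relative risk** (e.g. an odds ratio for a rare disease): implied
  carrier lifetime risk $r = \min(rr \times \text{baseline lifetime
  risk},\ 0.99)$ becomes the Beta prior mean for $\gamma$; the standard
  deviation comes from the CI width of $\log rr$ by the delta method, and
  the Beta shapes are moment-matched. Narrower CIs always give narrower
  priors.
- **Age-specific risk points.** A two-point table is read as labeled
  quartile points — first point = first-quartile age, second = median
  age, asymptote = twice the median-point risk (self-consistent with the
  usual way such quartiles are quoted). Three or more points are read as
  a cumulative-risk curve: the last point is the terminal plateau and the
  quartile ages are interpolated where the curve crosses a quarter and
  half of it. Beta shapes are centred at the reported ages (scaling
  anchored at the prior-mean threshold, 17.5y) with effective sample size
  equal to the study size, floored at the default prior's ESS and capped
  at 1000. The floor means a study of size 1 leaves the prior essentially
  at its default. The exact published translation is not reproducible
  from the available description; moment matching by mean and ESS was
  chosen as the simplest scheme with those two inputs.

## Pedigree likelihood

Families are single-locus Bayesian networks: founders draw genotypes from
Hardy–Weinberg at the supplied carrier prevalence (allele frequency
$f = 1 - \sqrt{1 - prev}$, so carrier mass equals the prevalence
exactly), children follow Mendelian segregation, and each member emits a
per-genotype phenotype likelihood:

| observation | contribution (per genotype class and sex) |
|---|---|
| affected at age $a$ | annual onset probability at $a$ |
| affected, onset age missing, censored at $c$ | cumulative onset by $c$ |
| unaffected / unknown status, censored at $c$ | $1 - F(c)$ |
| nothing observed | 1 |
| observed genotype | indicator multiplied in (carrier zeroes aa; noncarrier zeroes Aa, AA) |
| unknown sex | mean of the female and male values |

The likelihood is computed by sum–product variable elimination over
genotypes with a min-degree elimination order (C++), which is the
Elston–Stewart peeling recursion in its general form — linear in family
size for loop-free pedigrees. Factor tables are renormalized after every
elimination so log-likelihoods near $-\infty$ are handled without
underflow; data of probability zero return $-\infty$ with a warning.
Marriage and inbreeding loops are detected (cycles in the marriage-node
graph) and rejected rather than approximated, a documented limitation.
A brute-force $3^n$ enumeration engine (refusing $n > 15$) serves as the
independent oracle; the test suite requires agreement to $10^{-9}$
relative across randomized pedigrees, parameters, prevalences and
missingness patterns. Carrier posteriors for single members come from a
second peel with the member restricted to carrier states.

Ascertainment correction, when enabled, masks each proband's phenotype
while keeping the genotype observation, and excludes proband-only
singleton families. The likelihood is not additionally conditioned on the
proband's carrier status; since that probability depends only on the
(fixed) prevalence, it shifts the posterior by a constant.

## Adaptive Metropolis sampler

One block per sex (8 parameters when sex-specific, jointly updated;
4 otherwise). Proposals are Gaussian random walks with covariance
$s_d(\hat\Sigma + \epsilon I)$, $s_d = 2.38^2/d$, where $\hat\Sigma$ is
the running covariance of the chain history (Welford updates), switched
on at `adapt_start` (default 100); before that a diagonal covariance
proportional to the prior standard deviations (factor 0.05) is used.
$\epsilon$ (default $10^{-6}$) keeps proposals non-degenerate. Proposals
outside the bounds — threshold outside its prior support, ordering
violated, asymptote outside $(0,1)$ — are rejected before any likelihood
evaluation. Chains are initialized empirically: jittered 25th/50th
percentiles of observed onset ages per stratum, asymptote from the
proportion affected among genotyped carriers (clamped to $(0.05, 0.95)$),
threshold uniform below the minimum observed onset; strata without usable
onsets fall back to a prior draw (logged). Each chain gets its own
sub-seed derived from the master seed, so runs are reproducible and
independent of execution order; burn-in discards
$\lfloor burn\_in \times n\_iter \rfloor$ draws (floor, documented).

## Missing-age imputation

When enabled, missing ages are filled before each chain starts (onset
ages from the empirical onset pool of the same sex stratum with ±2-year
jitter, falling back to the baseline onset distribution; censoring ages
uniform on $[20, max\_age]$) and re-imputed every `impute_every`
iterations (default 100): for each target the member's carrier posterior
$w$ is computed under the current parameters with that member's own
onset masked, and the onset age is drawn from
$w\,\cdot$ (carrier onset distribution) $+\,(1-w)\,\cdot$ (baseline onset
distribution), truncated to the feasible window. This is a pragmatic
approximation — the age draw carries no Metropolis-within-Gibbs
correction, so the sampler targets the joint posterior only
approximately when imputation is active. With no missing ages the code
path is bypassed entirely and traces are bit-identical to a run without
imputation.

## The simulator: the stated world

`sim_design()` defaults describe a Lynch-syndrome-like study of a
mismatch-repair gene. Three generations around the proband: 4
grandparents, parents, aunts/uncles per side (Poisson mean 2.8) with
spouses and cousins (mean 1.5), proband siblings (mean 2) with spouses
and children (mean 1.5), and the proband's spouse and children (mean 2);
spouses enter only when the couple has children. The closed-form expected
family size (`expected_family_size()`) is ≈ 34.8, matching the
mid-thirties family sizes such studies report. Carrier prevalence
defaults to $5 \times 10^{-4}$; true penetrance defaults are quantile
parameterized (females $q_1=40$, $med=50$, $\gamma=0.5$, $\delta=20$;
males 38/48/0.6/18), consistent with published colorectal-cancer risk in
MLH1 carriers. The synthetic registry baseline reaches ≈ 4–5% lifetime
risk. Censoring ages are Gaussian per generation with means 82/70/57/32
(sd 8/8/10/8), calibrated so the simulated fraction of diagnosed
individuals (≈ 9.4%) matches the published study description's 428 of
4604; this calibration replaced an initial younger guess that produced
≈ 5% diagnosed. Ascertainment conditions on the proband carrying the
variant by rejection sampling of the proband's direct-ancestor core
(grandparents → parents → proband), after which remaining genotypes are
drawn forward — distributionally identical to whole-family rejection but
feasible at rare prevalence. Only the proband's genotype is observed by
default.

What the generator does **not** emulate: realistic mortality (censoring
is independent of disease), secular trends in family size, genotyping
error, de novo mutations, and multiple ascertainment pathways (e.g.
clinic referral of heavily affected families, which conditions on
phenotype, not just genotype). A green recovery test therefore
establishes correctness of the inference machinery under the model's own
assumptions — not robustness to their violation.

## Numerical and design choices

- Annual differencing (not midpoint densities) discretizes both carrier
  and baseline curves; telescoping guarantees total onset + never-onset
  mass equals one.
- Factor renormalization per elimination step bounds the dynamic range;
  the peel returns exact $-\infty$ for impossible data.
- Equal-tailed credible bands (order statistics, pointwise per age), not
  HPD and not joint bands; 50% bands are nested inside 95% by
  construction.
- Effective sample size uses Geyer's initial-positive-sequence
  truncation, capped at the chain length; split-chain $\hat R$ is floored
  at 1.
- Ties in discrete KS checks are handled by computing the exact KS
  distance on the age grid and comparing against the continuous critical
  value, which is conservative.
- Sex coding accepts 0/1, M/F and words; 0 = female. Parent references
  "0", empty and NA all mean missing. Unknown-sex members mix the two
  sex-specific likelihood values with equal weight.
- Multiple probands per family are allowed; proband removal masks all of
  them.

## Limitations

- **Extrapolation beyond follow-up is prior-driven.** The data identify
  the penetrance curve only up to the oldest censoring ages; the
  asymptote and the median onset age beyond that range are governed by
  the default priors, whose scaled-Beta(2, 2) median component centres
  near 70 years. At moderate study sizes (tens of families) the exact
  posterior can therefore sit on a ridge trading the median age against
  the asymptote and exclude the true $(med, \gamma)$ pair even though
  the curve itself is recovered accurately over the observed age range
  (the recovery tests measure both effects: curve error stays below 0.05
  mean absolute deviation while interval coverage for $med$ and $\gamma$
  falls short of nominal). Informative priors from published lifetime
  risks are the practical remedy.
- Looped pedigrees are rejected, not loop-broken.
- Imputation is approximate (no acceptance correction for age draws).
- One disease at a time; no competing risks; penetrance shape restricted
  to the modified Weibull family.
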