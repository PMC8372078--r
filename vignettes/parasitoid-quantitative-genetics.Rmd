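---
title: "Quantitative genetics of parasitoid performance on a novel host: models and methods"
author: "parasitoidQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of parasitoid performance on a novel host}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

parasitoidQG analyses standardized parasitization assays of a haplodiploid
wasp (a *Leptopilina*-type larval parasitoid) attacking a resistant novel
host (a *Drosophila* species with a strong encapsulation response). One
female is exposed for a few hours to 25 host larvae; the counts of emerging
adult flies (f), emerged flies carrying an encapsulated wasp egg (e, with
w = f − e capsule-free), and emerging wasps (p) are scored, together with
same-day unexposed control vials whose mean emergence n̄ estimates baseline
host survival. This vignette explains the models the package implements,
the choices behind them, and what the synthetic-data tests do and do not
demonstrate.

## Performance indices

With n̄ the day's control mean, the four indices are percentages:

* attack rate = 100 (n̄ − w)/n̄ — killed hosts plus survivors that carry a
  capsule, i.e. everything the wasp touched;
* killing rate = 100 (n̄ − f)/n̄ — excess mortality relative to unexposed
  controls, floored at 0 when more flies emerge than in the controls;
* lethal attack rate = 100 (n̄ − f)/(n̄ − w) — killing efficiency among
  attacked hosts, undefined when nothing was attacked;
* successful parasitism = 100 p/(n̄ − f) — wasp emergence per killed host,
  undefined when nothing was killed.

n̄ is a real number (a mean over ≥ 10 vials), so the denominators are
real-valued. Attack and lethal attack rates are clamped to [0, 100] and the
clamping is flagged; the conditional indices are reported as missing, not
zero, when their denominators are non-positive — a 0/0 assay carries no
evidence about efficiency and is excluded from downstream means.

Testing days whose control mean falls below 0.6 × the median of all days
are excluded by `qcFilterBlocks()` ("about half" the survival of the other
blocks indicates a bad host batch). The threshold is configurable; the rule
is a single pass with the median computed once.

## Haplodiploid relatedness

Males develop from unfertilized eggs and are haploid: a daughter receives
her sire's entire genome plus one maternal gamete, a son only a maternal
gamete. `haplodiploidAmatrix()` builds additive relationships a = 2f by the
tabular recursion (females: f(i,j) = (f(d,j) + f(s,j))/2, diagonal
(1 + f(d,s))/2; males: f(i,j) = f(d,j), diagonal 1). One internally
consistent convention — a = 2 × coancestry for every individual, male
self-relatedness 2 — is used throughout and validated against an
independent gene-dropping oracle (`geneDropCoancestry()`) rather than
against textbook constants: the oracle drops uniquely labelled founder
alleles through the pedigree and scores identity-by-descent. Full sisters
come out at a = 0.75, paternal half-sisters at 0.50. Because only diploid
females are phenotyped, the male diagonal convention never enters a
likelihood. Unknown parents are treated as unique unrelated founders, and
inbreeding is handled by the recursion. With `strict = FALSE`,
`buildPedigree()` accepts all-female two-parent pedigrees, in which the
same recursion reduces exactly to the standard diploid tabular method — a
cross-validation device, not a wasp pedigree.

## The liability-threshold animal model

Per assayed female i,

l_i = μ + a_i + d_{day(i)} + m_{mother(i)} + e_i,  e_i ~ N(0, V_r)

with breeding values a ~ N(0, V_a A) structured by the haplodiploid A
matrix, testing-day and mother effects iid, and V_r fixed at 1 (it is not
identifiable for binomial data; V_a scales with it, so h² is insensitive to
the choice). Heritability per posterior draw is

h² = V_a / (V_a + V_day + V_mother + V_r + V_link),

with V_link = 1 for the probit link. The probit is the default because the
h² correction "+1" is a probit link variance; a logit option replaces it by
π²/3. Point estimates are posterior modes of a Gaussian kernel density
(Silverman bandwidth); intervals are shortest empirical 95% HPD intervals.

### Priors and sampler

Each variance component carries a parameter-expanded scaled-χ²₁ prior:
V = α² with α ~ N(0, alpha_V). This is the large-ν limit of the common
parameter-expanded inverse-Wishart specification (V = 1, ν = 1000,
alpha.mu = 0, alpha.V = 1), under which the inner scale is a point mass at
V; the configuration accepts ν but the implementation fixes the inner
scale, which makes the prior exactly χ²₁ and lets a prior-predictive test
verify it by Kolmogorov–Smirnov. The sampler (Rcpp) uses

* a stepping-out slice update for each record's latent liability;
* collapsed updates for the expansion parameters: each α is slice-sampled
  from its marginal conditional with the corresponding Gaussian block
  integrated out (in the eigenbasis of A for the animal block, via
  per-level sufficient statistics for day and mother), then the block is
  redrawn conjugately. The naive α-given-effects Gibbs pair mixes along a
  funnel-shaped ridge; collapsing removes it (lag-1 autocorrelation of the
  retained V_a chain drops roughly by half at identical cost).

Every sweep is O(N²) through two matrix–vector products with the
eigenvector matrix. Defaults are 10,000 burn-in and 20,000 post-burn-in
iterations thinned to 2,000 retained draws; the recovery experiments in the
test-suite use 4,000/16,000/thin 8, verified by the diagnostics module
(effective sample size, lag-1 autocorrelation, Heidelberger–Welch
stationarity with the spectral density at zero estimated from an AR fit on
the second half of the chain). One caveat of the stationarity test is
worth knowing: because an autoregressive fit reproduces a straight line
exactly, a *near-deterministic* ramp inflates the spectral estimate and
escapes detection — the test is sensitive to drifts comparable to the
chain's noise (the regime that matters for MCMC), not to arbitrarily
steep ones.
Full-length runs of 910,000 samples are configuration, not code, changes.
Identical seed and configuration reproduce draws bit-identically.

### Two observation models

`method = "standardized_counts"` follows the conventional two-column
binomial coding: successes = round(n̄) − f (floored at zero),
trials = round(n̄), and successes ~ Binomial(trials, Φ(l)). Development of
this package showed that this coding *loses about half of the additive
variance* on synthetic data with known truth: the floor at zero compresses
all low-liability records onto the same count, and the baseline-mortality
noise in f is attributed by the model to the liability scale — a
regression-dilution effect that no rounding rule repairs.

`method = "survival_adjusted"` (the default when the data carry a
`day_survival` column) therefore moves the standardization into the
likelihood: the raw emerged count is modeled as
f ~ Binomial(n_larvae, s_day (1 − Φ(l))), with s_day = n̄/25 estimated from
the day's controls. For s_day = 1 the two models coincide. On synthetic
data the survival-adjusted model recovers the generating V_a essentially
unbiasedly where the count coding recovers about half. The two-column path
is retained because it is the conventional coding and is what a reanalysis
of archived data would start from.

### What recovery tests show — and a known limitation

On synthetic half-sib data at the design scale (68 sires, 115 dams, 345
daughters, 5 blocks, Binomial(25) assays, baseline survival 0.8) the 95%
HPD interval covers a true latent h² of 0.15 in 18/20 seeded replicates and
a true h² of 0 yields posterior modes below 0.05 in 20/20. At true
h² = 0.30 coverage drops to 16/20: the additive and mother components are
confounded (full sisters share both; only the 68-sire paternal-half-sib
contrast separates them, weakly under binomial noise), and the day variance
rests on five blocks, giving it a heavy posterior right tail that inflates
the h² denominator. Both effects persist under a nearly flat prior and with
model-consistent data, so they are properties of the design, not of the
sampler. Credible intervals from this design should be read accordingly:
they are honest about location but slightly too short in the upper tail
for strongly heritable traits.

## Synthetic data

`generateHalfsib()` emulates the breeding design: one sire × up to three
dams × three assayed daughters, with the dam-count distribution
(28 sires with one dam, 33 with two, 7 with three) as configuration —
published sire, dam and offspring totals recorded for such designs do not always reconcile exactly, so realized
totals (115 dams, 345 daughters) are reported rather than forced. Breeding
values use explicit gametic transmission (sire gamete variance V_a/2 shared
by all his daughters; dam contribution V_a/2 plus Mendelian sampling
V_a/4); liabilities add day, mother and unit residual effects; assay counts
are Binomial(25, s_day(1 − Φ(l))) and control vials
Binomial(25, s_day) with a small lognormal day factor on survival. A
mixed-model sib-analysis oracle (lme4 on the true liabilities) recovers the
configured V_a from the generated families, which validates transmission
independently of the Bayesian machinery. The generator reproduces the
*statistical* structure only: no behavior, no superparasitism, no real
encapsulation physiology (capsules are a fixed per-survivor probability,
0.25 by default) — so passing tests validate the estimators, not the
biology.

## Selection-experiment simulator

`runExperiment()` is genotype-explicit: 100 unlinked additive loci, founder
allelic values scaled so female breeding values have variance V_a
(n_loci = 100 approximates the infinitesimal model while keeping
Mendelian-sampling bookkeeping exact under haplodiploidy). Each of 3
selected and 3 control lines holds 100 assayed females per generation;
the top 50 by day-standardized killing rate (controls: 50 at random; ties
uniformly at random) each contribute 8 pupae sired by a random male of
their line, offspring mate among each other, and 100 daughters are assayed
next generation — for 7 generations. Females are spread over 3 testing days
per line and generation (the protocol reports 2–5), each day with its own
liability day effect and its own 10 control vials.

Host laboratory adaptation is the one modeling decision that goes beyond
the assay formulas. Baseline survival is flat to generation 2 and then
rises linearly to 1.30 × baseline (0.74 → 0.96) at generation 7. Because
day-standardization cancels a pure survival trend in expectation, a
survival-only drift cannot depress realized heritability; the simulator
therefore couples the trend to host *resistance* on the liability scale:

q = Φ(l − c·(Φ⁻¹(s_t) − Φ⁻¹(s_0))),

with coupling c = 1 by default — the survival rise and the resistance rise
are two faces of the same host-fitness improvement, measured in the same
probit units. Setting c = 0 recovers a pure survival drift (used in the
null tests). Under the default coupling, pooled realized heritability over
the first four generations averages ≈ 0.16 and declines thereafter — the
qualitative signature of a genetic response masked by a fitter host.

## Response analysis

`responsePoints()` computes per interval S = mean(selected parents) −
mean(all parents) and R = mean(offspring cohort) − mean(all parents) in
day-standardized killing percentages, with prefix sums per line;
`realizedHeritability()` is the no-intercept least squares slope
Σ(S_cum R_cum)/Σ(S_cum²) with its SE, F(1, n−1), adjusted R² and p-value.
Pooled ("average") estimates concatenate the three lines' points into a
single regression, which reproduces the characteristic degrees-of-freedom
pattern (12 points → F(1, 11) for the interval through generation four).
`selectionIntensity(p)` = φ(z)/p gives 0.798 for p = 0.5.
`breedersProjection()` propagates the per-generation latent gain
R = i·σ_a·√h²; since the latent-to-observed mapping of a threshold trait is
not unique, three mappings are exposed (unit probit — the default,
total-SD-scaled probit, and linear in percentage points) rather than
asserting one. From 24% with i = 0.79, σ_a = √1.077, h² = 0.281 the default
mapping reaches ≈ 99% after seven generations; the bracketing band 90–99.5%
is the package's claim, not an exact endpoint.

## Numerical and interface choices

* Rounding of count totals is half-away-from-zero (round(20.5) = 21), so
  totals never shrink systematically.
* HPD intervals are empirical shortest intervals; modes come from a kernel
  density with n = 1024 grid points.
* The relatedness eigendecomposition clamps eigenvalues at 10⁻¹⁰ and
  rejects matrices with materially negative eigenvalues.
* All tables are headered, comma-separated, UTF-8 text; every command-line
  run writes a JSON manifest (command, config, seed, package version, file
  digests) so outputs are regenerable from config + seed.
* Problem sizes in the shipped tests — 20-seed recovery experiments at the
  345-daughter design with 20,000-iteration chains, 2 × 10⁵ gene drops,
  20-seed selection simulations — were chosen so the full suite documents
  the statistical claims while remaining a desk-scale run.

## Known limitations

* The mother component is estimated from only ≤ 3 daughters per dam and is
  weakly separable from the additive component (see above).
* The survival-adjusted likelihood treats the day's control survival as
  known; its sampling error (≈ 0.02 with 10 vials) is ignored.
* The breeder's-equation projection deliberately refuses to pick a unique
  latent-to-observed mapping.
* Encapsulation enters the simulators as a fixed probability; the package
  does not model immune physiology, superparasitism or behavior.
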