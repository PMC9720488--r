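---
title: "Methods: resilience indicators, animal-model REML and mixed-model GWAS in layres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resilience indicators, animal-model REML and mixed-model GWAS in layres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layres)
```

`layres` analyses longitudinal egg production and natural-antibody (NAb)
titers of a single layer-hen batch: resilience indicators from
production deviations, heritabilities from a REML animal model, and a
single-SNP mixed-model genome-wide association study.  This vignette
documents the models, the tunable parameters, the synthetic-data
generator used for validation, and the numerical and design choices
made where the problem left room.

## 1. Resilience indicators

Weekly production is aggregated from egg-collection records taken at
1–4-day intervals.  Age-weeks are anchored at hatch: week $w$ covers
days of age $7(w-1)$ to $7w-1$.  Each collection record's eggs are
assigned entirely to the week containing its collection day; with
intervals of at most 4 days the attribution error is small and the rule
is deterministic.  A week enters the data only if collections cover all
seven of its days, so leading and trailing partial weeks (including the
week of death) are dropped rather than zero-filled.

Each hen's expected production is the batch mean curve — the across-hen
mean weekly count over the hens observed that week.  Deviations
$d_t = y_t - \bar y_t$ feed three per-period indicators:

* `LNvar` $= \ln s^2(d)$ with the $n-1$ sample variance;
* `Skew` $= m_3 / m_2^{3/2}$ with central moments on denominator $n$
  (the unadjusted Fisher–Pearson coefficient);
* `Rauto` $= \sum_{t}(d_t-\bar d)(d_{t+1}-\bar d) / \sum_t (d_t-\bar d)^2$,
  the serial estimator with a single mean and the full-series
  denominator, which is bounded in $[-1, 1]$.  A Pearson
  correlation-of-lagged-pairs variant is available
  (`lag1_autocorrelation(..., method = "pearson")`); the package's
  reference behaviour (including the constant-producer property below)
  holds under both.

Denominator conventions are deliberate choices — the most common
defaults in statistical practice — because the indicator literature
leaves them open; they are unit-tested against independent naive
implementations.

Periods are half-open week windows: 25–83 means weeks
$25 \le w < 83$, and 83–end runs from week 83 to the hen's last
observed week.  All three indicators are set missing when the hen laid
fewer than 20 eggs in a period; this removes spuriously extreme
autocorrelations of hens that barely laid.  With weekly data gaps
cannot arise by construction, but on irregular data pairs spanning a
gap are excluded from the `Rauto` numerator while the variance and
skewness use all present values.

A structural property of batch-mean referencing, used as an acceptance
check: a hen laying exactly 7 eggs every week from week 29 to week 92
against a batch curve declining linearly from 6.8 to 4.9 eggs/week has
strictly increasing deviations, and the serial lag-one autocorrelation
of a 64-point linear sequence is $0.9531 > 0.95$.  High `Rauto` (and
high `LNvar`) therefore flags low persistency as much as
disturbance-proneness — an interpretive limitation inherent to the
batch-mean reference, which individual expected curves (a configuration
hook left unimplemented) would trade against other difficulties.

## 2. SNP quality control

The cascade runs in a fixed order and is idempotent:

1. discard SNPs with a missing-call fraction strictly above 10 %;
2. within each SNP, set every genotype class with fewer than 10 hens to
   missing; on the Z chromosome also mask all heterozygous calls —
   hens (ZW) carry a single Z allele, coded homozygous-like 0/2, so a
   female Z heterozygote is an artefact;
3. discard SNPs with fewer than two classes of at least 10 hens, which
   could not support a categorical SNP effect.

"More than 10 %" and "fewer than 10" are strict inequalities;
missingness is assessed before masking (the narrative order of the
protocol).  The report's arithmetic closes exactly:
`input = retained + dropped_missingness + dropped_class_rule`.

## 3. Relationship matrices

The pedigree-based additive relationship matrix **A** uses the tabular
method on a parents-first ordering; unknown parents contribute zero.
The genomic matrix **G** is VanRaden's method 1,
$G = WW' / (2\sum_j p_j(1-p_j))$ with $W = M - 2p$, allele frequencies
observed in the genotyped sample (the founder frequencies of the base
population are unknown in practice), missing calls mean-imputed (zero
contribution) and monomorphic SNPs excluded from numerator and
denominator.  Because G estimated from a finite SNP panel can be
near-singular, `stabilize_grm()` blends $G^* = (1-w)G + wI$ with
$w = 0.01$ by default before it enters mixed-model equations.

## 4. Variance components

For each trait the animal model is
$y = Xb + a + e,\quad a \sim N(0, K\sigma^2_a),\quad e \sim N(0, I\sigma^2_e)$
with one record per animal and $K$ either **A** (variance-component
estimation on the full batch) or **G**.  Fixed effects are categorical:
plate (146 levels) and age at sampling (112/123/124/138 d) for NAb
titers; hatch week (3) and barn row (12) for indicators.  Hatch week is
excluded from the NAb model because it is confounded with sampling age;
the design-matrix builder drops aliased columns deterministically
(first occurrence kept) with a warning, so such confounding degrades to
a reduced-rank fit rather than an error.

Estimation profiles the restricted likelihood on the variance ratio
$\lambda = \sigma^2_a/\sigma^2_e$: after one spectral decomposition
$K = UDU'$, the rotated model has diagonal covariance
$\sigma^2_e(\lambda D + I)$, so the profiled REML log-likelihood is an
exact one-dimensional function of $\lambda$, maximised by Brent search
on $\log\lambda$ over $[10^{-6}, 10^6]$.  This is exact for the
single-random-effect model, cannot diverge, and lets many fits (e.g.
replicate simulations, eight traits) reuse one decomposition via
`kinship_eigen()`.  An iterative average-information updater would add
generality (multiple variance components) the model does not need.

Standard errors come from the inverse of the average-information matrix
$\mathrm{AI}_{k\ell} = \tfrac12\, y'P V_k P V_\ell P y$ evaluated at the
estimates, with the delta method for
$h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)$.  Degenerate designs are
flagged rather than hidden: with $K = I$ and one record per animal only
$\sigma^2_a + \sigma^2_e$ is identifiable, the profile is flat, and the
fit returns `converged = FALSE`.  Variance estimates are floored at
$10^{-8}\,\mathrm{var}(y)$; a maximum at the lower search bound is
reported as the boundary estimate $\hat\sigma^2_a = 0$.

The likelihood-ratio test for $\sigma^2_a = 0$ uses
$\Lambda = 2(\ell_{full} - \ell_{reduced})$ clipped at zero, where the
reduced model is the same fit at $\lambda = 0$.  Because the null value
sits on the boundary of the parameter space, the default reference
distribution is the equal mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$,
i.e. $p = \tfrac12 P(\chi^2_1 \ge \Lambda)$; the plain $\chi^2_1$
p-value is available with `mixture = FALSE` for comparability with
software that does not apply the boundary correction.

## 5. GWAS

Each SNP is tested by adding it to the trait model as a categorical
factor with one level per genotype class (reference level = most
frequent class), under $V \propto \mathrm{ratio}\cdot G + I$ with the
variance ratio fixed at the whole-batch REML estimate — the standard
fixed-ratio approximation that avoids re-estimating variance components
per SNP.  The significance measure is the conditional (incremental)
Wald F of the SNP factor given all other fixed effects, with numerator
degrees of freedom (number of filled classes − 1; Z-linked SNPs have at
most two classes in hens, hence 1 df) and denominator degrees of
freedom equal to the residual df of the GLS fit.  No Kenward–Roger or
Satterthwaite adjustment is applied: at $n$ in the hundreds to
thousands the difference is negligible, and the simple residual df is
reported explicitly.  Individuals with a missing call are excluded for
that SNP only (no imputation into a categorical design); the
implementation whitens the complete-call SNPs in one batched rotation
and refits the exact subset GLS for SNPs with missing calls.

Calibration and multiplicity follow the genomic-control / positive-FDR
conventions:

* inflation factor $\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$,
  converting every p-value to its 1-df $\chi^2$ quantile regardless of
  the test's df — the conventional scale on which $\lambda \approx 1$
  indicates calibrated tests;
* Storey q-values with $\hat\pi_0$ from the smoother: $\pi_0(\lambda)$
  on the grid $0.05, \dots, 0.95$, cubic smoothing spline (df = 3)
  evaluated at the grid maximum, clipped to $(0,1]$; with fewer than
  100 p-values the smoother is unreliable and $\hat\pi_0 = 1$, in which
  case q-values equal Benjamini–Hochberg adjusted p-values exactly;
* suggestive and significant calls at FDR 10 % and 5 % (strict `<`).

## 6. The synthetic batch generator

The generator exists so every stage can be validated end to end.  Its
defaults describe one realistic purebred batch:

* **Pedigree** — 2,494 hens in ~500 maternal families of 5 full sibs,
  dams nested within 125 sires, three hatch weeks at 2-week intervals in
  equal proportions.  Breeding values: founders $N(0, \sigma^2_a)$,
  offspring = parent average + Mendelian-sampling deviate of variance
  $\sigma^2_a/2$ (the non-inbred approximation — exact here because the
  pedigree is two generations deep with unrelated founders).
* **Genotypes** — 5,000 unlinked SNPs by default (a desk-scale stand-in
  for a post-QC 50 K array) across 10 autosomes and Z, founder allele
  frequencies uniform on [0.05, 0.5], founders in Hardy–Weinberg
  proportions, offspring by Mendelian gene dropping.  Females receive a
  single paternal Z allele coded 0/2.  Linkage and LD are deliberately
  not modelled: the downstream methods use SNPs marginally.
* **NAb titers** — titer = $\mu$ + plate + age class + breeding value +
  residual.  Hens are assigned to 146 plates in sampling order
  (balanced blocks of 8–9 for the 1,221-hen genotyped subset), plate
  effects $N(0, 0.05)$.  Age class follows hatch week (112 d for week
  1; 123 or 124 d for week 2; 138 d for week 3), reproducing the
  confounding that forces hatch week out of the NAb model.  Defaults
  calibrate IgM to mean 6.85, SD 1.21 with
  $h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e) = 0.39$
  ($\sigma^2_a = 0.551$, $\sigma^2_e = 0.862$), and IgG to mean 6.03,
  SD 1.33 with $h^2 = 0.20$.
* **Egg production** — each hen lays daily with probability
  $C_i(w)/7$, where $C_i(w)$ is her potential curve: the batch
  potential plus a genetic production level
  ($\sigma^2 = 0.09\,\mathrm{eggs}^2$), a barn-row effect
  ($\sigma^2 = 0.0025$), and after the peak a persistency multiplier
  ($\sigma^2 = 0.0225$, genetic correlation with level configurable,
  default 0) on the decline.  The batch target curve rises linearly
  from 0 at week 18 to 6.8 eggs/week at week 29 and declines linearly
  to 4.9 at week 92 — the simplest shape through the two anchor means.
  Disturbance episodes arrive as a Poisson process (0.02 per hen-week),
  depress the lay probability multiplicatively by a depth uniform on
  [0.2, 0.8], and decay exponentially with a 1.5-week time constant;
  the potential curve is calibrated (by root-finding per week) so that
  the realized batch mean — after the 7-egg cap applied to the
  individual-effect distribution and the expected steady-state
  disturbance burden $\rho\,\bar d\,\tau \approx 1.5\%$ — equals the
  target curve.  A constant culling hazard of 0.0024 per week truncates
  records at death (~16 % of hens before week 92, matching the order of
  magnitude of hens lacking a usable 83–end record).
* **Collections** — intervals of 1–4 days.  By default the schedule is
  aligned so a collection closes every age-week, which keeps weekly
  sums in [0, 7] under the no-proration aggregation rule.  With
  `allow_over7 = TRUE` the intervals free-run across week boundaries,
  occasionally misattributing eggs so a week registers more than 7 —
  the registration-offset mechanism behind rare >7 counts in real logs;
  it is off by default so the bounded-count invariant holds.

What the generator does *not* emulate: selection across generations,
genotype-by-environment interaction, LD structure, seasonal or barn
micro-environmental trends, and the dependence of culling on production.
Passing tests therefore validate the estimators under a correctly
specified polygenic world; they do not certify behaviour under model
misspecification found in real data.

## 7. Validation design and problem sizes

The test suite checks every computational claim against an independent
route: indicator formulas against naive direct implementations (and
`stats::acf` / `e1071::skewness` as external oracles), the A-matrix
against gene-dropping Monte Carlo on small pedigrees, REML against a
dense-matrix grid-plus-refine optimizer on 40-record fixtures, the
mixed-model SNP test against `anova(lm(...))` when the random effect
vanishes, and Storey q-values against Benjamini–Hochberg at
$\pi_0 = 1$.

End-to-end checks run on the generator's default batch: the lay-curve
anchors (6.8 at week 29, 4.9 at week 92, tolerance ±0.1) and the IgM
mean (6.85 ± 0.1); heritability recovery at $n = 2{,}494$ for true
$h^2 \in \{0.1, 0.2, 0.39\}$ — 100 replicates per value (reusing one
eigendecomposition) so the Monte-Carlo error of the estimated coverage
of $\pm 2\,\mathrm{SE}$ intervals stays near 1 % — and a fully null
polygenic scan (h² = 0.2, 1,221 genotyped hens, 5,000 SNPs) whose
GRM-corrected inflation factor must stay at or below 1.05 while the
uncorrected ANOVA scan visibly inflates.  Around $h^2 = 0.1$ the
plug-in Wald intervals are known to undercover slightly (~94 %); this
is a property of the interval, not an estimation bias — the estimates
themselves are unbiased to within Monte-Carlo error.

A note on batch-level drift: with ~500 maternal families from 125
sires, the mean breeding value of a batch has a standard deviation of
roughly 0.04 phenotypic SD for the NAb defaults, so simulated batch
means of IgM fluctuate around 6.85 by a few hundredths — single-batch
statistics inherit the family structure, and the ±0.1 tolerance absorbs
this by design.

## 8. Known limitations

* One record per animal: repeated measures and permanent-environment
  effects are out of scope, as are maternal effects (excluded from the
  final models after comparison in the motivating analysis) and
  multi-trait/genetic-correlation machinery.
* The fixed-ratio GWAS inherits the usual approximation of not
  re-estimating variance components per SNP; with a major locus the
  ratio would be slightly misspecified, which costs a little power but
  does not inflate the null.
* Genomic-control $\lambda$ on 5,000 SNPs has a Monte-Carlo standard
  deviation of roughly 0.04; occasional excursions above 1.05 at
  particular seeds reflect this noise, not miscalibration.
* The PLINK reader covers the plain-text .ped/.map dialect only, aimed
  at interoperability for small panels, not at scale.
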