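# layres

Resilience indicators, genetic parameters and mixed-model GWAS for laying
hens.

## The problem

Commercial layer batches are continuously exposed to disturbances — heat,
pathogens, management incidents.  A hen's *resilience* can be quantified
from her longitudinal egg-production record: compare observed weekly egg
counts with the expected production (the batch mean curve) and summarise
the deviations `d_t = observed_t − expected_t` into three indicators:

* **LNvar** = `ln(var(d))` — the log-variance of deviations (sample
  variance, denominator *n − 1*),
* **Skew** = `m3 / m2^{3/2}` — the moment skewness of deviations,
* **Rauto** = `Σ_t (d_t − d̄)(d_{t+1} − d̄) / Σ_t (d_t − d̄)²` — the
  lag-one autocorrelation of deviations.

Natural antibodies (NAbs, isotypes IgM and IgG binding the model antigen
KLH) serve as an indicator trait for general disease resistance.  For
breeding, two questions matter: how heritable are these traits, and are
there genomic regions of major effect?

`layres` implements the full analysis chain for a single hatch batch:

1. **Indicators** — weekly aggregation of 1–4-day egg-collection records,
   batch mean curve, deviations, and the three indicators for two laying
   periods (weeks 25–83 and 83 to end of life), with records set missing
   when a hen laid fewer than 20 eggs in a period.
2. **SNP QC** — discard SNPs with >10 % missing calls; mask genotype
   classes with <10 hens (and all Z-chromosome heterozygotes — hens carry
   a single Z allele); discard SNPs with fewer than two filled classes.
3. **Kinship** — pedigree A-matrix (tabular method) and VanRaden
   (method 1) genomic relationship matrix G, with optional identity
   blending for conditioning.
4. **Variance components** — REML animal model
   `y = Xb + a + e`, `a ~ N(0, K σ²_a)`, `e ~ N(0, I σ²_e)`, fitted
   exactly by profiling the restricted likelihood on the variance ratio
   after one spectral decomposition of K; heritability
   `h² = σ²_a/(σ²_a + σ²_e)` with delta-method SE from the
   average-information matrix; boundary-mixture likelihood-ratio test for
   σ²_a = 0.
5. **GWAS** — per-SNP mixed model with the SNP as a categorical factor
   (one level per genotype class), the variance ratio fixed at the
   whole-batch estimate, G correcting for family structure; conditional
   F-tests, genomic inflation factor
   `λ = median(χ²_obs)/median(χ²_1)`, Storey q-values, and FDR calls at
   10 % (suggestive) and 5 % (significant).
6. **Synthetic batch generator** — pedigree (maternal families in three
   hatch weeks), gene-dropped genotypes including hemizygous Z coding,
   NAb titers with plate and age-at-sampling effects, and a daily
   egg-laying process with genetic production level and persistency,
   Poisson disturbance episodes with exponential recovery, and culling —
   so the entire pipeline is testable without proprietary data.

## Worked example

```r
library(layres)

cfg <- sim_config(n_hens = 500, n_snps = 1000, n_genotyped = 250,
                  n_sires = 25, n_plates = 30)
res <- run_pipeline(cfg, seed = 1, traits = c("IgM", "r_auto_25-83"))
res$summary
```

```
         trait   n sigma_a2 sigma_e2    h2  se_h2    lrt_p lambda_gc n_suggestive n_significant
1          IgM 250    0.741   0.7611 0.493 0.1812 1.69e-05     1.019            0             0
2 r_auto_25-83 488    0.000   0.0275 0.000 0.0489 5.00e-01     0.952            0             0
```

Reading the output: for the simulated IgM titer the animal model
estimates `σ²_a = 0.74`, `σ²_e = 0.76`, i.e. `h² = 0.49` (SE 0.18 at this
small subset size), and the likelihood-ratio test rejects `σ²_a = 0`
(p = 1.7e-5).  The lag-one autocorrelation indicator in this small batch
shows no detectable genetic variance (boundary estimate, LRT p = 0.5).
Genomic inflation factors near 1 say the GRM-corrected per-SNP tests are
well calibrated; no SNP passes the 10 % or 5 % FDR thresholds, as
expected for polygenic traits with no major loci injected.

The QC report for the same run:

```
SNP quality control
  input SNPs:                1000
  dropped, missingness:      0
  masked calls (rare class): 1088
  masked calls (Z het):      0
  dropped, <2 filled classes:10
  retained:                  990
```

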