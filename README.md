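# crosstrait

Cross-disorder shared-locus analysis of GWAS summary statistics.

## What it is for

When two case-control GWAS of related disorders — e.g. schizophrenia
(SCZ) and bipolar disorder (BD) — share subjects, looking up one
study's index SNPs in the other produces spurious "shared" loci: the
shared cases and controls correlate the two studies' z-scores at every
SNP, and each study's polygenic inflation makes nominal p-values
anti-conservative on top. crosstrait implements the full lookup
pipeline with a principled correction for both effects, for analysts
who only have summary statistics (no genotypes) for either study.

## The model

At a null SNP the pair of z-scores is treated as bivariate normal with
marginal variances σ₁², σ₂² (mean of z² over a well-behaved SNP set)
and covariance

    c = [ nsc·√((n1ctl·n2ctl)/(n1case·n2case))
        + nsctl·√((n1case·n2case)/(n1ctl·n2ctl)) ] / √(N₁·N₂)

for `nsc` shared cases and `nsctl` shared controls (no genetic
correlation assumed). The corrected statistic for study 2 given study 1
is the standardized conditional residual

    z_corr = (z₂ − (c/σ₁²)·z₁) / √(σ₂² − c²/σ₁²),   p = 2·Φ(−|z_corr|)

The count of index SNPs with corrected p < 0.05 is tested against
Binomial(n, 0.05). Around it sit the standard stages: conditional-
Gaussian (ImpG-style) z-score imputation from an LD panel, √N-weighted
z-score meta-analysis (METAL's sample-size scheme), allele
harmonization, Bonferroni reporting over both lookup directions, and
INRICH-style LD-interval gene-set enrichment with permutation and
min-p resampling correction. A synthetic-data generator
(`simulate_pair()`) produces paired z-score sets with known overlap,
inflation, LD and shared loci so every stage can be validated without
cohort data.

## Worked example

Two studies of 35,476/46,839 and 9,747/14,278 cases/controls sharing
500 cases and 9,200 controls, with z-variances 1.82 and 1.24:

```r
library(crosstrait)

spec  <- overlap_spec(n1_case = 35476, n1_control = 46839,
                      n2_case = 9747,  n2_control = 14278,
                      ns_case = 500,   ns_control = 9200)
model <- build_null(var1 = 1.82, var2 = 1.24,
                    cov = theoretical_overlap_cov(spec))
model
#> Bivariate null: var1 = 1.8200, var2 = 1.2400, cov = 0.1644 (corr = 0.1094)

# synthetic pair of studies with 20 truly shared loci among 20,000 SNPs
cfg <- simulation_config(n_snps = 20000, n_blocks = 1000,
                         shared_fraction = 0.001, shared_effect_z = 4,
                         seed = 42)
sim <- simulate_pair(cfg)

# index list: the 20 shared loci plus 87 null SNPs, looked up in study 2
idx_ids <- c(sim$truth$snp_id[sim$truth$shared],
             setdiff(sim$study1$snp_id,
                     sim$truth$snp_id[sim$truth$shared])[1:87])
idx <- sim$study1[sim$study1$snp_id %in% idx_ids, ]

ct <- conditional_transform(
  sim$study1$z[match(idx$snp_id, sim$study1$snp_id)],
  sim$study2$z[match(idx$snp_id, sim$study2$snp_id)], model)
build_report(idx, ct$p_corrected, m = 111, alpha = 0.05)
#> Shared-locus report
#>   107 input, 0 on X, 0 indels -> 107 mappable, 107 tested
#>   27 of 107 nominal at alpha = 0.05 (binomial p = 2.28e-12)
#>   9 survive Bonferroni at m = 111
```

The 27 nominal hits are the 20 planted shared loci plus 7 that reach
p < 0.05 by chance or borderline power; the binomial p-value says a
27/107 hit rate is incompatible with the 5% expected under no sharing.
`run_pipeline()` chains all stages (impute → meta → correct → report →
gene sets) from one YAML config, and `exec/crosstrait` wraps it for the
shell.

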