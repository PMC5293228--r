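---
title: "Cross-disorder shared-locus analysis from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-disorder shared-locus analysis from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstrait)
```

## The problem

Two psychiatric case-control GWAS — say a schizophrenia (SCZ) discovery
study and a bipolar disorder (BD) study — often recruit from the same
control registries and sometimes share patients. If we take the SCZ
index SNPs and simply look up their p-values in the BD study, two things
corrupt the answer:

1. **Sample overlap.** Shared subjects induce a correlation between the
   two studies' association z-scores at *every* SNP, even under the
   null, so SCZ hits look spuriously "shared" with BD.
2. **Polygenic inflation.** Each study's z-scores have marginal variance
   above 1 (polygenicity plus residual confounding), so nominal
   p-values from `2*pnorm(-|z|)` are anti-conservative.

crosstrait models the pair of z-scores at a SNP as bivariate normal and
tests sharedness on the *conditional* distribution of the second study's
z-score given the first, which removes both distortions at once.

## The bivariate null and the conditional transform

At a null SNP let \(z_1, z_2\) be the two studies' z-scores with
marginal variances \(\sigma_1^2, \sigma_2^2\) (estimated as the mean of
\(z^2\) over a well-imputed SNP set, `estimate_inflation()`) and
covariance \(c\). For case-control studies with \(n_{s,case}\) shared
cases and \(n_{s,ctl}\) shared controls,

\[
c \;=\; \frac{n_{s,case}\sqrt{\frac{n_{1,ctl}\,n_{2,ctl}}{n_{1,case}\,n_{2,case}}}
 \;+\; n_{s,ctl}\sqrt{\frac{n_{1,case}\,n_{2,case}}{n_{1,ctl}\,n_{2,ctl}}}}
 {\sqrt{N_1 N_2}},
\]

assuming no genetic correlation contributes
(`theoretical_overlap_cov()`). The same quantity can be estimated from
data as the intercept of a regression of \(z_1 z_2\) products on LD
scores (`empirical_overlap_cov()`), which the genetic signal cannot
contaminate because it loads on the slope.

The corrected statistic is the standardized conditional residual

\[
z_{corr} = \frac{z_2 - (c/\sigma_1^2)\, z_1}
                {\sqrt{\sigma_2^2 - c^2/\sigma_1^2}},
\qquad p_{corr} = 2\Phi(-|z_{corr}|).
\]

Standardizing by the *full* marginal \(\sigma_2^2\) — which includes
polygenic inflation, not just the overlap term — makes the test
deliberately conservative: true polygenic signal in the denominator can
only shrink \(|z_{corr}|\). We consider that the right default when the
question is "which individual loci are shared", where false positives
are costlier than false negatives; `variance_mode = "unit"` substitutes
1 for \(\sigma_2^2\) as a sensitivity analysis. Both directions of
conditioning are available (`swap_null()`): index SNPs of study 1 looked
up in study 2, and vice versa.

```{r}
spec <- overlap_spec(n1_case = 35476, n1_control = 46839,
                     n2_case = 9747, n2_control = 14278,
                     ns_case = 500, ns_control = 9200)
model <- build_null(var1 = 1.82, var2 = 1.24,
                    cov = theoretical_overlap_cov(spec))
model
```

With ~500 shared cases and ~9,200 shared controls between studies of
roughly 82k and 24k subjects, the overlap covariance is about 0.164 and
the implied z-score correlation about 0.109 — small, but enough to
inflate a 107-SNP lookup badly if ignored (see the calibration section).

## Surrounding stages

**Imputation** (`impute_block()`). When the two studies were imputed to
different reference panels, index SNPs may be missing from one of them.
We treat the z-scores in an LD block as a zero-mean multivariate normal
with covariance equal to the LD correlation matrix and impute an untyped
SNP by its conditional mean given the typed SNPs, with a ridge term
\(\lambda\) on the typed-typed correlation submatrix. The predicted
accuracy \(r^2_{pred} = w'(\Sigma+\lambda I)^{-1}w\) is reported per SNP
and is 1 for typed SNPs. \(\lambda\) defaults to 0.1, the customary
regularizer for this estimator; imputation is strictly per-block, which
keeps the linear algebra local and mirrors how windowed
summary-statistic imputation is run in practice. No accuracy filter is
applied by default (`min_r2pred = 0`); the distribution is reported so
users can choose a gate.

**Meta-analysis** (`meta_analyze()`). Two target-study files are
combined by the sample-size-weighted scheme,
\(z = \sum_i \sqrt{N_i}\, z_i / \sqrt{\sum_i N_i}\), after allele
harmonization (`harmonize()`, which resolves swapped and
strand-complementary allele encodings and flags A/T and C/G SNPs as
strand-ambiguous rather than guessing). Total N is the default weight;
effective N, \(4/(1/n_{case}+1/n_{ctl})\), is available for unbalanced
designs. No inverse-variance scheme is provided: the pipeline operates
on z-scores, not betas.

**Shared-locus report** (`map_snps()`, `build_report()`). Index SNPs on
the X chromosome and indels are excluded before lookup (the imputation
model covers autosomal SNVs), then intersected with the target study.
Hits are counted at strict `p < 0.05`; the familywise report multiplies
by the number of tests in *both* lookup directions (Bonferroni), and the
headline count is tested for enrichment against Binomial(n tested,
0.05) — under the null, each corrected p-value is uniform, so the count
of nominal hits is binomial regardless of the traits involved.

**Gene-set stage** (`build_intervals()`, `test_gene_sets()`). Around
each shared SNP we build an LD interval spanning all panel SNPs with
\(r^2 \ge 0.5\) to the index SNP (threshold configurable; overlapping
intervals are merged so they are LD-independent, and a BD index SNP in
\(r^2 > 0.8\) with an SCZ index SNP is excluded from the reverse lookup
as the same signal). Genes are assigned with 50 kb flanks; a gene set's
statistic is the number of intervals hitting at least one member gene.
The null relocates each interval uniformly in the annotated genome,
preserving its length and its gene-count class (±1 gene, by rejection
sampling with a bounded number of tries), giving
\(p = (1+\#\{perm \ge obs\})/(R+1)\); a second resampling stage scores
\(B\) fresh null datasets against the same null to correct the best-set
p-value familywise (min-p resampling, floored at the first-stage p so
the corrected value never undercuts the empirical one). Defaults
\(R = 10{,}000\), \(B = 1{,}000\), set sizes 10-200 after intersection
with the annotation universe.

## What the simulator emulates — and what it does not

`simulate_pair()` draws z-scores directly: per block, a latent AR-1
correlation matrix (parameter `ld_decay`; closed-form structure makes
oracle checks easy), and per SNP a bivariate normal with the configured
marginal variances and the overlap covariance implied by the
`overlap_spec`. Truly shared loci get a mean shift of `shared_effect_z`
with a common sign in both studies. The defaults are the study setting
above: variances 1.82 and 1.24, overlap 500/9,200, `ld_decay = 0`
(independent z-scores, matching the assumption that index SNPs come
from distinct LD regions), `shared_effect_z = 4` — a typical
non-centrality for a replicable index SNP.

Deliberately *not* modeled: genotypes, allele frequencies, realistic
MAF/LD spectra, linkage of inflation to LD scores, and X-chromosome
dosage. Passing tests therefore demonstrate that the estimators and the
correction are right *under the stated model*, not that the model
captures every feature of real GWAS data; in particular the simulator
cannot validate the choice of the HapMap3-style SNP set used to
estimate inflation on real data.

## Numerical choices

- LD matrices are repaired to positive semi-definite at load by
  eigenvalue clipping (tolerance 1e-8) and re-normalized to unit
  diagonal; the ridge \(\lambda\) guards the typed submatrix separately.
- \(r^2_{pred}\) is clipped to [0, 1]; tiny negatives arise from finite
  precision only.
- Ties in the report are broken by chromosome then position; Bonferroni
  values above 0.9999 are displayed as ">0.9999" while the exact value
  is retained in the data.
- All randomness flows from a single integer seed per entry point;
  permutation results are reproducible bit-for-bit.
- A SNP present in only one target study is meta-analyzed as that study
  (the weight normalization handles it); `require_all` restricts to the
  intersection instead.
- A record with a p-value but no direction column is rejected rather
  than assigned an unsigned |z|; silent sign errors are the worst
  failure mode of summary-statistic pipelines.

## Calibration, and a caveat on exact permutation tests

On a fully null simulated pair at the default overlap/inflation setting
(10^5 SNPs), the corrected p-values are uniform: the nominal-hit rate is
0.05 within Monte-Carlo error, while the *uncorrected* rate is roughly
double — the correction is not optional at this degree of overlap. The
test suite runs exactly this experiment.

The gene-set stage's empirical p-value is exact but discrete: with a
handful of intervals the observed statistic takes few values, so the
probability of `empirical_p < 0.05` under the null sits *below* 0.05
(measured 0.02-0.03 across configurations) rather than at it. This is a
property of every exact permutation test, not a defect; the suite
checks validity (rate ≤ nominal) and agreement with an exhaustively
enumerated relocation null on a toy genome.

## Known limitations

- The overlap covariance formula assumes the shared subjects play the
  same role (case/control) in both studies and no genetic correlation;
  when traits are genetically correlated the theoretical value
  understates the product-moment covariance, which is why the
  LDSC-intercept estimator is provided as a cross-check.
- Inflation estimates depend on the SNP set supplied; the package does
  not ship a reference SNP list.
- Gene-count-class matching in the permutation null is an approximation
  to density-matched backgrounds; with a bounded rejection budget,
  hard-to-match intervals fall back to unmatched relocation.
- Problem sizes in the shipped tests (10^5 SNPs for calibration, toy
  genomes for enumeration) were chosen so that each property is
  measured with adequate Monte-Carlo precision while the whole suite
  stays quick to run.
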