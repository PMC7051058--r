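---
title: "Two-stage age-by-genotype interaction analysis: models and methods"
author: "ageGWIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage age-by-genotype interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Genome-wide association studies of treatment response usually estimate a
single marginal SNP effect. When the pharmacogenetic architecture differs
between children and adults — as it plausibly does for inhaled
corticosteroid (ICS) response in asthma — the informative quantity is not
the marginal effect but the *age-by-genotype interaction*: how the
per-allele log-odds of poor response changes per unit of (transformed)
age. ageGWIS implements a two-stage genome-wide interaction study (GWIS)
for a binary response outcome (poor responder = at least one exacerbation
on therapy, good responder = none) with a continuous exposure, together
with the simulation machinery needed to validate every stage of the
pipeline against known truth.

## The interaction model

At each variant $j$ with additive minor-allele dosage
$G_j \in [0, 2]$, exposure $E$ and covariates $X$:

$$
\operatorname{logit} P(Y = 1) =
  \beta_0 + \beta_G G_j + \beta_E E + \beta_I\, G_j E + \gamma' X
$$

The test statistic is the Wald $z = \hat\beta_I / \widehat{se}$ with
two-sided $P = 2(1 - \Phi(|z|))$ and 95% CI
$\exp(\hat\beta_I \pm 1.96\,\widehat{se})$. The fit is maximum-likelihood
logistic regression by iteratively reweighted least squares, implemented
in compiled code because a genome-wide null-calibration run evaluates
$10^5$ fits. `glm()` and a direct quasi-Newton likelihood maximiser serve
as independent oracles in the test suite; the IRLS path agrees with them
to $10^{-6}$ on small fixtures.

Wald (rather than likelihood-ratio) inference matches the convention of
the standard GWAS toolchain for interaction terms. Quasi-complete
separation is *detected and flagged*, not corrected: a fit with any
$|\hat\beta| > 15$ or an unstabilised deviance is marked
`converged = FALSE`, retained in the per-variant output, and excluded
from downstream filtering. No Firth penalty is applied, since the
procedure being reimplemented used none.

### Exposure transformation

Age distributions in pooled pediatric/adult cohorts are right-skewed
with influential extremes, so raw age is mapped to normal quantiles by a
rank-based inverse-normal transform with Blom offsets,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for ties. The
choice of the Blom constant is a design decision — the source procedure
says only "quantile-normalized" — and is immaterial beyond third-decimal
differences in the transformed values. The transform is applied *within
each stage*, because the stages were analysed separately. When a cohort
already carries a transformed exposure (as simulated cohorts do), that
value is used directly.

### Covariates

The conventional adjustment set is sex, BMI (untransformed), study
indicators (one-hot, first level as reference) and the first six genotype
principal components. PCA standardises each variant by
$\sqrt{2p(1-p)}$, mean-imputes missing calls to zero after centring, and
flags samples beyond 6 SD on any returned component; exclusion decisions
are left to the analyst.

## Variant quality control

Exclusion is strictly below each threshold, matching the stated rules:
MAF < 1%, call rate < 90%, imputation INFO < 0.9, and Hardy-Weinberg
exact $P < 10^{-5}$; values exactly at a threshold pass. The HWE test is
the exact conditional test computed by enumerating every heterozygote
count compatible with the observed allele counts via a numerically stable
recurrence from the modal configuration (no mid-$P$), on hard calls
(dosage rounded) over all samples — the de facto standard. Where the QC
history of a real dataset involved separate pre- and post-imputation
rounds with overlapping thresholds, this module applies one consolidated
pass.

## Two-stage filtering and joint analysis

Discovery associations at the genome-wide *suggestive* level
($P < 10^{-5}$) are carried to replication; variants also nominally
significant there ($P < 0.05$) **and** with concordant interaction-effect
signs are combined with the sample-size-weighted Z-score method:

$$
z_{\text{joint}} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}},
\qquad w_i = \sqrt{n_i},
\qquad z_i = s_i\, \Phi^{-1}(1 - p_i / 2),
$$

with $s_i$ the sign of the stage's $\hat\beta_I$, and joint significance
declared at $P < 5 \times 10^{-8}$. The $\sqrt{n}$ weights are the METAL
convention; the source only says "a weighted Z-score method". Stage
sample sizes default to 783 (discovery) and 538 (replication) but are
taken from per-variant `n` when available.

Two caveats worth recording. First, published joint $P$ values in this
design cannot generally be recovered from *rounded* stage-level $P$
values: the maximum attainable combined $|Z|$ from the rounded inputs
can fall short of what a printed joint $P$ requires. Joint-analysis
correctness here is therefore established by oracle equivalence (closed
form and root-finding inversion to $10^{-10}$), not by matching printed
joint columns. Second, published "replicated" tables can contain rows
whose discovery $P$ slightly exceeds the stated $10^{-5}$ filter; this
package applies the stated thresholds strictly.

## The synthetic-cohort generator

The generator produces exactly the structure the analysis and the power
calculation assume, and nothing more:

* genotypes: two independent Bernoulli($p$) allele draws per sample
  (HWE by construction), default MAF 0.49 — the frequency of the
  top-ranked signal;
* exposure: $E \sim N(0, 1)$, i.e. already on the transformed-age scale;
  a raw `age` column is derived as a fixed monotone log-normal map
  ($\exp(3 + 0.5E)$ years, median ~20, right-skewed) so the
  transformation path can be exercised;
* outcome: Bernoulli draws from the logistic model with default
  coefficients $\beta_0 = -0.32$, $\beta_G = 0.17$, $\beta_E = 0.97$ —
  the estimates reported for the discovery population. Outcomes are
  drawn unconditionally and cases/controls labelled post hoc, so the
  407/376 discovery split is matched in expectation only, exactly as the
  original power analysis did;
* covariates: sex ~ Bernoulli(0.5), BMI ~ $N(26, 4^2)$, study uniform
  over its levels, all independent of $G$ and $E$ (no distributions were
  specified for them; independence keeps the null clean);
* multi-variant cohorts: the single-SNP generative model is generalised
  to $m$ variants with a designated causal subset so genome-wide filters
  have a testable target; non-causal variants are fully null and
  independent.

One root seed is split into named streams (genotypes, exposure, outcome,
covariates, missingness), so enlarging the variant panel never perturbs
the exposure draws, and identical parameters give byte-identical
cohorts.

The default interaction coefficient is $\beta_I = -0.875$, the midpoint
of the $-1.00 \ldots -0.75$ grid used in the power analysis. The sign is
deliberately left free: the source quotes a *negative* grid but a
*positive* (0.8) in-study estimate, an inconsistency this package does
not resolve.

What the generator does **not** emulate: linkage disequilibrium,
imputation uncertainty, ascertainment (case/control sampling),
population stratification, or covariate confounding. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to those real-data features. A
two-subpopulation allele-frequency shift is used in tests only as a PCA
fixture.

## Empirical power calculation

Power for the interaction test is estimated by brute-force simulation,
reproducing the published calculator's design: simulate a cohort
(default $n = 783$), fit the *unadjusted* model (intercept, $G$, $E$,
$G\!\times\!E$ — no covariates, as the original specifies), and count
rejections at $\alpha$ (default $5\times10^{-8}$) over `nReps` (default
10,000) replicates, across the $\beta_I$ grid $-1.00$ to $-0.75$ by
0.05. Non-converged replicates are excluded from the denominator and
reported separately (the original does not say how failures were
handled). Each estimate carries its Monte-Carlo standard error
$\sqrt{\hat\pi(1-\hat\pi)/n_\text{reps}}$. An analytic Wald-approximation
oracle (non-centrality from the expected information, integrated
numerically over $G$ and $E$) cross-checks the simulation in the test
suite.

## Candidate-gene proxy annotation

Each candidate gene (e.g. *DPP10*, *HDAC9*, *TBXAS1*, *FBXL7*,
*GSDMB/ORMDL3*) is represented by its proxy: the lowest-P variant within
the gene body extended by 10 kb on both sides. Decisions the source
leaves open, resolved here: windows are gene body ± flank (not TSS ±
flank); bounds are inclusive; coordinates 1-based with BED converted on
read; ties on P break by position, then id. A BED of the candidate genes
with *synthetic* placeholder coordinates ships under `inst/extdata/` for
demonstration only — real analyses must supply their own coordinates on
the correct build.

## Numerical choices and degenerate inputs

* IRLS: deviance-change convergence at relative tolerance $10^{-8}$,
  25-iteration cap, working weights floored at $10^{-10}$; rank-deficient
  designs (e.g. monomorphic dosage) yield `NA` estimates with
  `converged = FALSE` rather than an error.
* HWE: monomorphic sites have a single attainable configuration and
  $P = 1$; the two-sided sum uses a $1 + 10^{-10}$ relative guard when
  comparing configuration probabilities, the standard protection against
  ties lost to floating-point rounding.
* Signed-Z conversion switches to log-scale quantiles below
  $P < 10^{-300}$ to avoid underflow.
* Inverse-normal transform of a constant vector returns all zeros (tied
  average ranks map to the median quantile).
* MAF of an all-missing variant is undefined and excluded by the MAF
  rule with `NA` recorded.

## Calibration experiment sizes

The validation suite runs: type-I error of the interaction test at
$n = 783$ over 5,000 null simulations (accepted band 0.04–0.06 at
$\alpha = 0.05$); HWE null rejections over 2,100 HWE cohorts of 1,000
samples (bound $10^{-3}$ at $P < 10^{-5}$); genomic inflation
$\lambda$ over 100,000 null variants drawn as 100 independent cohorts of
1,000 variants (band 0.98–1.02) — many moderate cohorts rather than one
large one, because $\lambda$ computed within a single finite cohort is a
conditional quantity whose cohort-to-cohort spread exceeds its
Monte-Carlo error; interaction-coefficient recovery within $\pm 0.05$ at
$n = 50{,}000$; power-curve properties at 2,000 replicates per point;
and a planted-signal end-to-end run (100 seeded two-stage studies,
783/538, one causal variant at $\beta_I = -1$ among 20) requiring the
causal variant to pass all filters and rank first on joint $P$ in at
least 90% of replicates.

## Known limitations

* Inference is Wald-based throughout; no score/LRT variants, no
  robust (sandwich) standard errors, no case-only G×E test.
* Meta-analysis is the weighted-Z combination only — no inverse-variance
  fixed/random effects, no heterogeneity statistics.
* QC does not cover cross-array harmonisation, strand flips, relatedness
  or duplicate detection; phasing and imputation of real arrays are out
  of scope.
* The Wald interaction test shows a small finite-sample inflation of
  the median test statistic at $n \approx 800$ (conditional $\lambda$
  per cohort roughly 0.98–1.03); this is a property of Wald logistic
  inference at these sample sizes, not of the implementation, and is
  why the $\lambda$ calibration averages over cohorts.
* Binary PLINK bed/bim/fam is not parsed; convert with
  `plink --recode vcf` or equivalent.
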