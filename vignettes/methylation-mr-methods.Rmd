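---
title: "Appraising causal effects of DNA methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising causal effects of DNA methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Blood DNA methylation at CpG sites such as cg05575921-*AHRR* is strongly
associated with lung cancer risk in prospective epigenome-wide association
studies (EWAS). Whether those associations are causal is a different
question: smoking lowers methylation at these sites *and* raises cancer
risk, so an observational odds ratio can arise entirely from confounding
(including residual confounding after adjusting for self-reported smoking),
or from reverse causation. `mqtlmr` implements the analytic chain used to
adjudicate this: matched-pair EWAS, fixed-effects meta-analysis, genetic
instrument construction from methylation quantitative trait loci (mQTLs),
and one- and two-sample Mendelian randomization (MR) with sensitivity
analyses — together with a synthetic-data generator that reproduces the
statistical structure of the problem so every stage can be verified without
access to consortium data.

# The generative model

`sim_config()`/`simulate_cohort()` state one explicit world. A standardized
"smoking burden" $C \sim N(0,1)$ confounds both arms. Methylation at a
single CpG is simulated on the M-value (logit2) scale,

$$M = \mu + \textstyle\sum_j \beta_{GP,j} G_j + \gamma C + \varepsilon,
\qquad \beta = \frac{2^M}{2^M + 1},$$

with $G_j \sim \text{Binomial}(2, \text{maf}_j)$ independent cis-SNPs and
$\varepsilon \sim N(0, \sigma^2)$. Disease is Bernoulli with

$$\operatorname{logit} P(D = 1) = \alpha + \theta \tilde\beta + \delta C,$$

where $\tilde\beta$ is methylation standardized to SD units on the beta
scale, so $\theta$ is a log odds ratio per SD of methylation — the causal
effect under test. When survival fields are requested, an exponential event
time with log-hazard $\propto \theta\tilde\beta + \delta C$ is drawn and
censored administratively.

Why simulate on the M scale? The reported quantity is the beta value in
$[0,1]$, but the field reports effects per SD and gives no generative model
for beta values; logit-scale simulation guarantees valid support and the SD
standardization on the beta scale makes "OR per SD increase" exact. The
inverse-logit transform is monotone and, over the bulk of the data, close
enough to linear that a SNP explaining $r^2$ of M-value variance explains
almost the same fraction of beta-value variance (the tests correct for the
transform via the empirical correlation of the two scales).

## Default parameter values (the stated world)

| parameter | default | units | why |
|---|---|---|---|
| `n_individuals` | 20 000 | people | two-sample cohort scale used by the acceptance checks |
| `n_snps`, `maf` | 4, 0.30 | — | few independent common cis-mQTLs, the typical instrument architecture |
| `beta_gp` | sized for 2% | M-value per allele | per-SNP variance explained ~2%, inside the 0.8–10% range seen for real mQTLs |
| `theta` | 0 | log-OR per SD | the central scenario: no causal effect |
| `gamma` | −0.5 | M-value per SD of burden | smoking lowers methylation |
| `delta` | 0.7 | log-OR per SD of burden | smoking raises disease risk |
| `base_logodds` | −3 | — | ~5% cumulative incidence, a realistic cohort rate |
| `n_pairs` | 918 | pairs | the scale of a pooled four-cohort matched EWAS |

With these defaults the observational association is OR ≈ 0.75 per SD while
the genetic (MR) estimate is centred on OR 1.00 — confounding-induced
separation, which is precisely what the two-sample design is meant to
expose.

Matched pairs are drawn by exact greedy matching in random order on
discretized covariates (numeric covariates are cut into tertiles); the
matching algorithm in the original cohort studies is not described, so exact
matching was chosen as the simplest scheme whose contract (identical
discretized covariate values within every pair, unmatched cases counted) is
testable. Smoking strata (`never`/`former`/`current`) are tertiles of the
continuous burden; which covariates are matched is configuration, not a
fixed choice, because the source cohorts differed in whether they matched on
smoking.

## What the generator does *not* emulate

No 450k probe chemistry, batch structure beyond the single confounder,
region-level correlation between CpGs, or realistic LD (an LD matrix can be
supplied where the analysis consumes one). A green test therefore
establishes that the *estimators* behave as specified under the stated
statistical structure — not that any particular biological dataset would
reproduce the original study's numbers.

# Estimators

**Conditional logistic EWAS.** For 1:1 pairs the conditional likelihood
reduces to intercept-free logistic regression on within-pair covariate
differences; `conditional_logistic()` maximizes it by Newton–Raphson with
the observed-information SE, scaling methylation to SD units first. The test
suite checks it against an independent difference-logistic oracle to 1e-6
and against closed forms (differences (+1,+1,+1,−1) give log-OR = ln 3).
Complete separation is flagged via divergence diagnostics rather than
silently reported.

**Surrogate variables.** The iterative surrogate variable algorithm is out
of scope; `surrogate_variables()` returns the leading principal components
of the methylation matrix after residualizing on the protected design. This
preserves the testable contract — orthonormal sample-level components,
ordered by variance explained, capturing unmodelled structure — and defaults
to k = 10 components, the count used in the original adjustment models.
**Cell proportions** are reference-based constrained least squares
(non-negative, sum to one), solved by Lawson–Hanson NNLS with a sum-to-one
penalty row; no biological reference ships with the package — tests build a
synthetic one.

**Meta-analysis.** METAL-style fixed-effects inverse-variance pooling is
implemented directly ($w_i = 1/se_i^2$), with Cochran's
$Q = \sum w_i (b_i - \hat b)^2$, $I^2 = \max(0, (Q - df)/Q)$, a per-study
direction string (zeros are sign-neutral glyphs, documented), step-up
Benjamini–Hochberg FDR, and Kruskal–Wallis + Dunn comparison of adjustment
models (Dunn pairwise p-values Bonferroni-adjusted by default — the choice
is configurable since no adjustment was named).

**Instruments.** Greedy p-ordered LD pruning at r² < 0.01 with
lexicographic tie-breaks (deterministic; the source analysis names only the
threshold), instrument strength by the t-statistic identity
$r^2 = t^2/(t^2 + n - 2)$, $F = t^2$ (robust to scaling conventions; the
$2\,\text{maf}(1-\text{maf})\beta^2$ route is also exported), replication
flags requiring FDR < 0.05 *and* directional concordance, a 1 Mb cis window
with trans instruments admitted only behind an explicit flag, and a
summary-level scan of instruments against behaviour-trait GWAS tables that
separates nominal from FDR-significant hits.

**Two-sample MR.** Harmonization aligns effect alleles (sign flips,
complement-strand resolution, logged actions) and drops palindromic SNPs
whose allele frequency on either side lies in (0.42, 0.58). The Wald ratio
$\hat\theta = \beta_{GD}/\beta_{GP}$ carries a first-order delta-method SE
by default (a second-order correction and an outcome-only SE are available
by flag); multiple ratios are pooled by fixed-effects IVW with Q attached.
MR-Egger is weighted least squares with a free intercept after orienting
all exposure effects positive; the InSIDE assumption is not testable and
not claimed. Correlated-instrument IVW solves the ratio regression through
the origin under outcome-effect covariance
$\Omega_{ij} = se_{GD,i}\, se_{GD,j}\, \rho_{ij}$ and requires a positive
definite $\rho$ (eigenvalues are reported otherwise); with $\rho = I$ it
reduces exactly to IVW with outcome-only weights — the weighting described
as "inverse variance of the associations with the outcome" — which is why
that reduction, not the delta-SE version, is the tested identity.

**Power.** `mr_power()` uses the binary-outcome non-centrality
approximation $\text{ncp} = N K (1-K) r^2 (\ln \text{OR})^2$; the original
power analysis names only its inputs, so this standard approximation is
adopted and documented as such.

**One-sample MR.** A methylation-increasing allele score (negative-weight
SNPs have dosage reflected), two-stage Cox regression — stage 1 linear,
stage 2 `survival::coxph()` on fitted methylation — with a nonparametric
bootstrap CI over individuals, because the source analysis does not state
how two-stage SEs were obtained; the naive model-based interval is reported
alongside with an explicit caveat that it ignores stage-1 uncertainty.

# Numerical choices and degenerate inputs

* Newton iterations stop at step < 1e-10 (50 max); |coefficient| > 15 is
  treated as probable separation.
* All-zero within-pair differences, constant allele scores, zero-variance
  methylation matrices, non-positive SEs, out-of-range p-values and
  non-positive-definite correlation matrices raise errors rather than
  propagating NaN.
* Monomorphic SNPs are flagged in exports, never dropped; unmatched cases
  and rejected input rows are counted and reported.
* M-values are computed with beta values clipped to [1e-6, 1 - 1e-6].
* All randomness flows from explicit integer seeds;
  `two_sample_replicate(i)` derives both cohort sub-seeds from seed i, so
  whole pipelines re-run byte-identically.

# Known limitations

* Logistic and Cox effect measures are non-collapsible: with strong
  residual variance in the linear predictor, marginal genotype-disease
  coefficients are mildly attenuated relative to the conditional causal
  parameter. The parameter-recovery checks therefore plant effects in
  unconfounded worlds where the attenuation is far below Monte-Carlo
  resolution; in the confounded null scenario the estimand is exactly zero
  and no attenuation arises.
* The generator's confounded-null separation is probabilistic: at the
  default confounding strength the observational estimate is ~N(−0.29,
  0.053) on the log scale, so a single 918-pair study lands below OR 0.8
  about 89% of the time — a bound demanding 95% at the 0.8 cutoff is not
  attainable in this world and the corresponding acceptance check is left
  red by design rather than quietly re-parameterized.
* BH adjusted p-values are not a fixed point of re-adjustment except for
  degenerate (constant) sequences; the suite tests the true invariants
  (monotonicity, dominance over raw p, agreement with `p.adjust`).
* 1:1 conditional likelihood only; general m:n strata, time-varying
  covariates, competing risks, weighted-median/mode MR estimators and
  winner's-curse corrections are out of scope.
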