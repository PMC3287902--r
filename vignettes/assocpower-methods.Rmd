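---
title: "Score-test power with multiple causal variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-test power with multiple causal variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocpower)
```

## The trait model

Everything in this package is built on an additive quantitative-trait
model for $N$ unrelated individuals with $J$ diallelic causal SNPs and
$K$ measured covariates:

$$
Y \;=\; \mu \;+\; \sum_{k=1}^{K} \alpha_k Z_k \;+\; \sum_{j=1}^{J} \beta_j X_j \;+\; \varepsilon .
$$

$Y$ is the trait vector, $\mu$ a constant baseline, $Z_k$ the covariate
vectors with effects $\alpha_k$, and $X_j$ the genotype vectors coded as
minor-allele counts (0/1/2), so $\beta_j$ is the trait change per copy of
the minor allele. The model assumes no gene--gene or gene--environment
interactions and unrelated individuals. The error law is not dictated by
the score-test framework; we take $\varepsilon \sim N(0, \sigma^2)$
i.i.d., the standard choice and the one consistent with the chi-square
null distribution of the test statistic. `trait_model()` holds
$(\mu, \alpha, \beta, \sigma)$; `simulate_traits()` draws replicate
trait vectors with genotypes and covariates held fixed and only
$\varepsilon$ redrawn, which is the replicate-phenotype design under
which "simulated power" is defined here.

## The score test

For a test SNP $\tau$, let $\tilde X_\tau$ and $\tilde Y$ be the
residuals of $X_\tau$ and $Y$ after least-squares regression on
$Z = (\mathbf 1, Z_1, \dots, Z_K)$. The score statistic and its null
variance estimate are

$$
u = \langle \tilde X_\tau, \tilde Y \rangle, \qquad
v = s_{YY}\, \lVert \tilde X_\tau \rVert^2, \qquad
s_{YY} = \frac{\lVert \tilde Y \rVert^2}{N-1},
$$

and $u^2/v$ is referred to $\chi^2_1$. Two conventions deserve a note:

* **$s_{YY}$ divisor.** We use $N-1$, under which the unadjusted test
  collapses exactly to the classical identity
  $u^2/v = (N-1)\,r^2_{X_\tau Y}$ — the identity the test suite uses as
  an independent oracle. The alternative $N-K-1$ is available via
  `syy_divisor = "residual_df"`; for the sample sizes this package
  targets (hundreds of individuals, a handful of covariates) the two
  differ by a factor $(N-1)/(N-K-1)$ of order $1 + K/N$ and are
  practically indistinguishable.
* **Per-replicate $s_{YY}$.** In simulations, $s_{YY}$ is estimated from
  each replicate's own residuals, never pooled across replicates: each
  replicate is analysed the way a real data set would be.

`collapsed_score_test()` applies the identical machinery to the weighted
pseudo-genotype $\sum_i w_i X_i$, which is how rare variants are tested
jointly (burden-style collapsing); the pseudo-SNP is accepted everywhere
a SNP is, including the power machinery.

## Power: the multi-causal noncentrality parameter

Under the trait model, $u^2/v$ at SNP $\tau$ is noncentral
$\chi^2_1(\lambda)$ with

$$
\lambda \;=\; (N-1)\,\Bigl(\sum_{j} r_{\tau j}\, h_j\Bigr)^{2},
\qquad
h_j = \beta_j \sqrt{\frac{s_{jj}}{s_{YY}}},
\qquad
s_{j_1 j_2} = \frac{\langle \tilde X_{j_1}, \tilde X_{j_2}\rangle}{N-1},
$$

where $r_{\tau j} = s_{\tau j} / \sqrt{s_{\tau\tau}\, s_{jj}}$ is the
covariate-adjusted sample correlation between the genotype vectors and
$h_j$ the *direct effect* of causal SNP $j$: $h_j^2$ is the fraction of
the adjusted trait variance SNP $j$ explains. With one causal SNP tested
at itself this degenerates to $\lambda = (N-1)h^2$, the classical
single-SNP formula; the multi-causal form is its extension, and the
per-causal products $r_{\tau j} h_j$ are exactly what
`noncentrality()` tabulates.

Two numerical choices matter here:

* **Which $s_{YY}$ enters $h_j$.** For *analytical* power the package
  uses the model-implied adjusted trait variance
  (`model_residual_variance()`):
  $s_{YY} = \sigma^2 + \beta^\top S \beta$ with $S$ the adjusted
  genotype covariance matrix of the causal SNPs. This is the "true
  $\beta$" analysis: no independence among causal SNPs is assumed — their
  sample covariances enter in full. The *empirical* $s_{YY}$ is used
  only inside the score test itself.
* **Power function.** `analytical_power(lambda, alpha)` is the
  upper-tail mass of $\chi^2_1(\lambda)$ beyond the central
  $\chi^2_1$ critical value; at $\lambda = 0$ it returns exactly
  $\alpha$.

### The hyper-LD effect

The cumulative sum $\sum_j r_{\tau j} h_j$ is squared *after*
aggregation, which has a consequence that is easy to underestimate: ten
causal SNPs each with $r_{\tau j} = 0.1$ and direct effect $h$ yield
$\lambda = (N-1)h^2$ — one hundred times, not ten times, the $\lambda$
of a single such SNP. Power at a test SNP therefore reflects the
*collective* effect of every causal SNP it is even weakly correlated
with. Because sample correlations between independent common SNPs are
approximately $N(0, 1/N)$, about 1% of them exceed
$2.33/\sqrt N$ ($\approx 0.088$ at $N = 697$) by chance alone, so the
contributing SNPs need not be near the test SNP nor in genuine LD with
it. The `correlation_scan()` / `count_correlated()` /
`null_panel_comparison()` pipeline measures this directly, and
`cumulative_effect_report()` produces the per-test-SNP diagnosis.

Rare SNPs (tens of minor-allele copies) have positively skewed
finite-sample correlation distributions and accumulate more chance
exceedances; and between a common and a rare causal SNP with equal
$\beta$, the common one contributes more to tests at the rare one than
vice versa ($r$ is symmetric but $h_{\text{common}} > h_{\text{rare}}$).
Both behaviours are asserted by the test suite on engineered panels.

## Hyper-LD scan conventions

* **Sign of the threshold.** Counting partners with $r > t$ (signed,
  the default) and with $|r| > t$ are both meaningful; under
  minor-allele coding the sign of $r$ is convention-dependent, so the
  choice is exposed as `signed`. The default follows the literal
  "$r_{\tau j} > 0.1$" reading.
* **Distance exclusion.** Same-chromosome pairs closer than 10 Mb are
  excluded from scans and counts by default, so that the counts measure
  *long-range* correlation rather than ordinary local LD. Pairs on
  different chromosomes are never excluded. The exclusion applies only
  to the counting pipeline — `cumulative_effect_report()` deliberately
  sums over *all* causal SNPs, since nearby causal SNPs contribute to
  power like any others.
* **Adjustment.** $r_{\tau j}$ is defined as a covariate-adjusted
  correlation, so scans adjust by default; raw correlations are obtained
  by passing no covariates.
* **Streaming kernel.** Correlations are computed blockwise
  (`block_size` columns at a time, default 512) so peak memory scales
  with the block size and panel width, not with the number of pairs;
  the output is invariant to the block size (tested).

## Data model and quality control

Genotypes are always minor-allele counts. The VCF reader flips a site's
coding when ALT is the in-sample major allele; an exact 0.5 frequency is
resolved by treating ALT (or the allele written "1" in TSV input) as
minor — deterministic and documented. Missing genotypes are excluded
pairwise from MAF computation, and mean-imputed per SNP inside the score
test and correlation machinery so $N$ stays constant; monomorphic SNPs
are retained by readers but skipped (with a message) by tests and scans,
since their adjusted variance is zero.

HWE quality control tests each population separately and filters on the
minimum per-population p-value, default threshold $10^{-4}$. The default
test is the exact conditional test (the distribution of the heterozygote
count given allele counts, mid-less p-value), which is the common GWAS
QC choice and is validated in the suite against an independent log-gamma
enumeration; the 1-df goodness-of-fit chi-square is available as an
option. Monomorphic columns get $p = 1$ by convention.

## What the simulators emulate — and what they do not

`simulate_genotypes_independent()` draws Binomial(2, MAF) genotypes:
SNPs in HWE and exact linkage equilibrium, the null model against which
chance correlation is measured. `simulate_genotypes_ld()` draws two
haplotypes per individual from explicit per-block haplotype frequency
tables, giving genuine within-block LD and cross-block independence;
`random_ld_blocks()` builds such tables by an allele-copy mechanism with
expected anchor--partner correlation near `copy_prob`. Synthetic SNPs
are laid out 1 Mb apart, 1000 SNPs per chromosome, so the 10 Mb
exclusion rule is exercisable. The default covariate spec emulates a
typical exome-panel covariate set — Age (uniform 18--80 years), Sex
(Bernoulli 0.5), Smoke (Bernoulli 0.25) and a 7-level Population factor
with equal frequencies, mirroring a 697-individual, seven-population
design; the smoking rate and age range are generic choices of the
package, not estimates of any particular cohort.

These generators reproduce the *statistical* structure the analytics
assume — HWE, block LD, additive effects, normal errors, fixed genotypes
across replicates. They do not attempt population-genetic realism: no
coalescent history, no admixture or relatedness, no haplotype-length
distribution, no genotyping error, and no gene--gene or
gene--environment interaction. Passing tests therefore validate the
mathematics and the implementation, not the behaviour of the method
under model violations such as cryptic relatedness or non-normal traits.

## Numerical choices and degenerate inputs

Residualization uses a QR least-squares solve of the
$[\mathbf 1 \mid Z]$ design; a rank-deficient design is an error naming
the collinear columns, and residual orthogonality is kept to a relative
$10^{-8}$. A SNP whose residual is numerically zero (relative
$10^{-12}$) is treated as degenerate: an error for a single test, a
logged skip in scans. A trait fully explained by the covariates yields
$u = 0$, $\chi^2 = 0$, $p = 1$ rather than a 0/0. Correlations are
clamped to $[-1, 1]$ against rounding. All simulators take an explicit
seed, restore the caller's RNG stream, and are bit-reproducible; the CLI
derives per-stage substreams from one global seed so stages can be rerun
independently.

## Problem sizes used by the test suite

The suite validates the analytics at sizes a laptop handles in seconds:
$N = 697$ (the sample size at which the worked threshold
$2.33/\sqrt N = 0.088$ is stated) for the null-correlation, type-I-error
and power-agreement checks; 6,000--20,000 simulated independent SNP
pairs for the 1%-tail and variance-$1/N$ checks; a 500-SNP panel with 10
causal SNPs in LD blocks and 100 trait replicates for the
analytical-vs-simulated power comparison; 2,000 replicates for type-I
error and the $E[u^2/v] = 1 + \lambda$ identity. Effect sizes
$\beta \in [0.08, 0.30]$ with $\sigma = 1$ were chosen once to spread
analytical power over roughly $(0.1, 0.99)$ so the comparison is
informative across the range.

## Known limitations

* Quantitative traits only; the logistic/binary-trait approximation is
  out of scope.
* No mixed-model or kinship adjustment; individuals are assumed
  unrelated, and population structure is handled only through fixed
  covariates.
* Haplotype-based LD measures ($D'$, phased $r^2$) and LD pruning are
  not provided; all correlations are genotypic sample correlations.
* No multi-allelic sites, imputation, phasing or sex-chromosome
  handling.
* The analytical power treats the genotype panel (hence every
  $r_{\tau j}$ and $s_{jj}$) as fixed; it answers "what is the power at
  these genotypes", not an expectation over genotype resampling.
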