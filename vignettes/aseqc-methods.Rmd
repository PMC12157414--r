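---
title: "Sample-level ASE quality control with aseqc: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-level ASE quality control with aseqc: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseqc)
```

## The problem

Allele-specific expression (ASE) compares reference- and alternate-allele
read counts at a sample's heterozygous sites. In a clean sample, the
allelic ratios of most genes sit near one half, spread out by binomial
sampling noise, cis-regulatory variation, and a systematic tilt toward the
reference allele from alignment (reference bias). Several technical failure
modes — above all reads that originate from a *different individual* than
the genotype used for ASE calling — distort allelic ratios transcriptome
wide. A contaminated or otherwise degraded sample shows more spread in its
allelic ratios than binomial sampling alone can explain, across essentially
all genes at once.

`aseqc` turns that observation into a per-sample score and a cohort-level
pass/fail decision.

## The model

For gene $i$ in sample $j$, let $r_{ij}$ and $a_{ij}$ be reference and
alternate read counts and $t_{ij} = r_{ij} + a_{ij}$. Counts are modelled
with a binomial whose success probability has a normally distributed logit
(the binomial logit-normal, BLN):

$$r_{ij} \mid \lambda_{ij} \sim \mathrm{Bin}(t_{ij}, \lambda_{ij}),
\qquad \mathrm{logit}(\lambda_{ij}) \sim \mathcal{N}(\mu_j, \sigma_j^2).$$

$\mu_j$ is the mean log allelic fold change — in practice mostly reference
bias — and $\sigma_j$ is the cross-gene spread of log allelic imbalance,
the *extra-binomial* dispersion. $\sigma_j$ is the quantity of interest:
the aseQC score $\sigma(\mathrm{BLN})$. The latent per-gene ratio
$\lambda_{ij}$ is integrated out, never estimated per gene.

A handful of high-count genes at extreme imbalance (mono-allelic
expression, imprinting, genotyping errors) can drive the BLN likelihood to
underflow. A small uniform component guards against this:

$$p(r \mid t) = (1 - \varepsilon)\,\mathrm{BLN}(r; t, \mu, \sigma) +
\varepsilon \, \frac{1}{t + 1},$$

with $\varepsilon = 10^{-3}$ by default. The uniform component is read as
the *discrete* uniform on $\{0, \dots, t\}$ (mass $1/(t+1)$): the mixture
then mixes two probability mass functions on the same support, and
normalization is exact. With $\varepsilon > 0$ no observation can
contribute $-\infty$, so the fit is robust to a few wild genes without
modelling them. `epsilon = 0` is accepted (the pure BLN) but documented as
an unsupported configuration for production QC.

Per sample, $(\hat\mu_j, \hat\sigma_j)$ maximise
$\sum_i \log p(r_{ij} \mid t_{ij})$ over the genes retained by the count
filter.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `min_total`, `max_total` | 5, 5000 | inclusive bounds on $t$; genes outside are ignored. Shallow genes carry almost no dispersion information; ultra-deep genes would dominate the likelihood and are often artefacts. |
| `epsilon` | $10^{-3}$ | uniform mixture weight (dimensionless) |
| `mu_bounds` | $[-5, 5]$ | log allelic fold change |
| `sigma_bounds` | $[10^{-3}, 5]$ | log allelic fold change; the lower limit keeps the quadrature well-posed, the upper is far above any plausible sample |
| `n_quadrature_nodes` | 61 | Gauss–Hermite order |
| `min_genes` | 50 | fewer genes after filtering is reported as insufficient data, not as a silently unreliable estimate |
| `max_restarts` | 5 | perturbed restarts on non-convergence |
| `tolerance` | $10^{-8}$ | objective tolerance, mapped to L-BFGS-B `factr` |

## Numerical choices

**Quadrature.** The BLN pmf is a one-dimensional integral over the latent
logit ratio $u$. A fixed Gauss–Hermite rule centred on the *prior*
$\mathcal{N}(\mu, \sigma^2)$ loses the integrand entirely when the
binomial term is much narrower than the prior (large $t$, large $\sigma$:
at $t = 5000$, $\sigma = 3$ the likelihood peak is ~40× narrower than the
node spacing). `aseqc` therefore uses *adaptive* Gauss–Hermite quadrature:
per record, the mode of
$g(u) = \log \mathrm{Bin}(r; t, \mathrm{logit}^{-1}(u)) + \log
\mathcal{N}(u; \mu, \sigma^2)$ is found by damped Newton iteration ($g$ is
strictly concave, so this is globally convergent), nodes are centred there
and scaled by $1/\sqrt{-g''}$, and the weighted sum is accumulated with
log-sum-exp. With 61 nodes the result agrees with adaptive interval
quadrature to better than $10^{-9}$ in log-pmf across depths up to 5000
and $\sigma$ up to 3; the test suite asserts $10^{-6}$ against an
independently coded `stats::integrate` oracle.

**Optimisation.** The negative log-likelihood is minimised with L-BFGS-B
under the box bounds above. The gradient is analytic: differentiating the
marginal log-pmf under the integral sign gives posterior expectations of
the prior score, evaluated with the quadrature's posterior node weights
(the node centres' own parameter dependence contributes only at
quadrature-error order; the tests verify the gradient against central
finite differences). The start point is moment-based:
$\mu_0 = \mathrm{logit}\!\big((\sum_i r_i + 0.5)/(\sum_i t_i + 1)\big)$,
$\sigma_0 = 0.5$. If the optimiser reports non-convergence, up to
`max_restarts` perturbed starts are tried; perturbations are drawn under a
seed derived from a hash of the sample id, so fits are bit-reproducible and
never touch the caller's RNG stream.

**Degenerate inputs.** Perfectly balanced data ($r = t/2$ everywhere)
drives $\hat\sigma$ to its lower bound, which is the correct boundary MLE.
Duplicate gene ids within a sample are a validation error (aggregation must
happen first). Samples with fewer than `min_genes` usable genes are soft
failures in cohort runs: they appear in the output with
`status = "insufficient_data"` and are flagged as failing QC, but never
abort the run — batch processing across thousands of samples should not
stop on one thin library.

## Outlier detection

Cohort aseQC scores are right-skewed even in clean data, so a plain Tukey
boxplot over-flags. `aseqc` uses the medcouple-adjusted boxplot of Hubert
and Vandervieren: with $\mathrm{MC}$ the medcouple of the converged scores
and $\mathrm{IQR} = q_3 - q_1$ (type-7 quartiles),

$$\sigma_t = q_3 + 1.5\, e^{3\,\mathrm{MC}}\, \mathrm{IQR}
\quad (\mathrm{MC} \ge 0), \qquad
\sigma_t = q_3 + 1.5\, e^{4\,\mathrm{MC}}\, \mathrm{IQR}
\quad (\mathrm{MC} < 0),$$

and a sample fails exactly when $\hat\sigma > \sigma_t$ (strict
inequality; a score equal to the threshold passes). The medcouple is
computed by the exact $O(n^2)$ all-pairs kernel, including the sign kernel
for observations tied at the median; cohorts are at most tens of thousands
of samples per tissue, where this costs well under a second, so the fast
$O(n \log n)$ algorithm is deliberately out of scope.

Three choices here were genuinely open:

* $\sigma_t$ is reported as the upper *fence*, not the largest observation
  inside it (the whisker). Under the strict-inequality rule the two flag
  identical sample sets, and the fence has the advantage of not depending
  on which particular observations the cohort happened to contain.
* Fits that did not converge (or had insufficient data) are excluded from
  threshold estimation and flagged as failing with an annotation. Including
  them could corrupt the quartiles with boundary values; silently passing
  them would hide real failures.
* Only the upper fence flags: abnormally *low* dispersion is not a known
  failure mode of ASE data.

Multi-tissue designs are handled by running the pipeline once per tissue;
the tool itself never stratifies.

## The synthetic cohort generator

`simulate_ase_sample()` draws each gene's depth from a configurable law
(uniform on $\{20, \dots, 200\}$ by default, or a rounded lognormal clipped
to $[5, 5000]$ so the default count filter never removes simulated genes),
the latent ratio from the BLN prior, and reads by binomial sampling.
Defaults ($\mu = 0.1$ for mild reference bias, $\sigma = 0.3$,
5000 genes) represent a clean bulk RNA-seq sample of realistic size.

Genotype-mismatch contamination at fraction $c$ is modelled at the
allelic-count level: at each host-heterozygous gene the contaminator's
genotype is hom-ref, het, or hom-alt with Hardy–Weinberg probabilities at
allele frequency one half ($0.25/0.5/0.25$, configurable), contributing
expected reference ratio $1$, an independent logit-normal draw, or $0$; the
effective ratio is $p = (1-c)\lambda + c\lambda_{\text{cont}}$. The
contaminator is stochastic per gene rather than one fixed individual — a
deliberate abstraction of the real setting where a single contaminator's
genotypes vary across sites.

`simulate_benchmark_cohort()` reproduces the graded-contamination design:
21 quadratically spaced levels $(k/20)^2$, $k = 0..20$, with a truth table.
The design is *paired*: a replicate keeps one seed stream across all
levels (contaminator draws are made unconditionally and reads are sampled
by inversion), so the same "source sample" is re-mixed at increasing
fractions, exactly as when one sequencing library is resampled at graded
contamination, and level effects are not confounded with between-sample
noise.

What the generator does **not** emulate: read-level phenomena (alignment
and mapping-bias artefacts, blacklisted regions, phasing errors), a fixed
contaminator individual with linkage between sites, variation in gene
number or depth profile between samples, and biological covariance between
a gene's expression level and its allelic imbalance. Passing tests on
synthetic cohorts therefore demonstrate that the estimator and threshold
behave correctly under the stated generative model — not that real
cohorts are free of effects the generator omits.

## The low-contamination dilution effect

One property of count-level ratio mixing deserves a warning. For small
$c$, mixing a sample's ratios toward an *independent* contaminator
compresses the cross-gene spread of logit ratios at first order in $c$
(every gene is pulled toward a common reference point), while the
hom-ref/hom-alt mismatch separation that inflates the spread grows only as
$c^2$. At a clean-sample dispersion of $\sigma = 0.3$ the fitted score
therefore *dips* slightly (by $\sim 0.007$) over $c \in (0, 0.04)$ before
rising steeply — by 46% at $c = 0.25$ in the shipped benchmark. The mean
score is consequently not a strictly monotone function of the
contamination fraction at very low levels, although heavily contaminated
samples separate from clean ones without difficulty (the end-to-end
benchmark flags every $c = 0.25$ sample with zero false positives). The
acceptance report computes both quantities (`contamination_spearman_low_range`,
`contamination_sigma_inflation_c25`) so the effect is visible rather than
hidden.

## Problem sizes in the shipped tests

The test and acceptance suites run at sizes chosen to exercise the
estimator in its operating regime while keeping a full run on a laptop
within minutes: 50-replicate calibration at 5000 and 500 genes, a
9-level × 5-replicate contamination benchmark at 5000 genes, and a
53-sample detection cohort (50 clean, 3 contaminated at $c = 0.25$).
Quadrature and medcouple checks run against independent oracles on
deterministic stress grids (depths to 5000, $\sigma$ to 3, vector lengths
3–200 with and without ties).

## Known limitations

* $\hat\mu$ summarises reference bias; the package neither corrects it nor
  performs per-gene ASE outlier testing — those are different tools'
  jobs. Gene-level aggregation keeps a single most-expressed variant per
  gene, discarding multi-variant information.
* The threshold is per cohort. Scores are comparable across cohorts only
  insofar as depth profiles and gene counts are; thresholds are not.
* Very small cohorts (a handful of samples) make quartiles and the
  medcouple unstable; the hard minimum is 3 converged fits, but thresholds
  from such cohorts should be treated as indicative only.
* The $O(n^2)$ medcouple is quadratic in cohort size; beyond ~$10^5$
  samples per cohort it would become the bottleneck.
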