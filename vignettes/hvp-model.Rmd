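---
title: "Separating horizontal and vertical pleiotropy in genetic correlation estimation"
author: "pleiodecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating horizontal and vertical pleiotropy in genetic correlation estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiodecomp)
```

## The problem

A genome-wide genetic correlation between two complex traits is usually
read as evidence of shared biology: variants that affect both traits
directly (*horizontal pleiotropy*). But the same correlation arises when
variants affect an exposure that in turn causally affects the outcome
(*vertical pleiotropy*). Standard estimators — bivariate GREML on
individual-level data, or LD score regression on summary statistics — do
not distinguish the two, so a purely causal trait pair can show a large
"genetic correlation" and a non-heritable outcome can look heritable.

`pleiodecomp` implements a correction that removes the vertical-pleiotropy
contribution from genetic covariance, genetic variance, heritability and
genetic correlation, given an estimate of the causal effect, and provides
delta-method standard errors, liability-scale transformations for binary
traits, and a summary-statistics path with block-jackknife uncertainty.

## The model

For a standardized outcome $y$ and exposure $c$,

$$
y = c\,\tau + \alpha + e, \qquad c = \beta + \epsilon,
$$

where $\tau$ is the fixed causal effect of $c$ on $y$, $\alpha$ and
$\beta$ are the aggregate genetic values of the two traits and $e$,
$\epsilon$ the residuals. The quantity of biological interest is the
horizontal-pleiotropy block: $\mathrm{cov}(\alpha, \beta)$,
$\mathrm{var}(\alpha)$, and the genetic correlation
$r_G = \mathrm{cov}(\alpha,\beta)/\sqrt{\mathrm{var}(\alpha)\,\mathrm{var}(\beta)}$.

The standard bivariate model ignores $\tau$ and fits
$y = g + \gamma$ with $g = \alpha + \tau \beta$ and
$\gamma = e + \tau \epsilon$. Its genetic components are therefore biased:

$$
\mathrm{var}(g) = \mathrm{var}(\alpha) + \tau^2 \mathrm{var}(\beta)
  + 2\tau\,\mathrm{cov}(\alpha, \beta), \qquad
\mathrm{cov}(g, \beta) = \mathrm{cov}(\alpha, \beta) + \tau\,\mathrm{var}(\beta).
$$

Given $\tau$, the package inverts these relations:

* `correctGencov()`: $\mathrm{cov}(\alpha,\beta) = \mathrm{cov}(g,\beta) - \tau\,\mathrm{var}(\beta)$;
* `correctGenvar()`: $\mathrm{var}(\alpha) = \mathrm{var}(g) - \tau^2\mathrm{var}(\beta) - 2\tau\,[\mathrm{cov}(g,\beta) - \tau\,\mathrm{var}(\beta)]$;
* `correctedH2()`: $h^2 = \mathrm{var}(\alpha)/\mathrm{var}(y)$, which is
  $\mathrm{var}(\alpha)$ itself for a standardized outcome;
* `correctedRg()`: the corrected correlation assembled from the above.

These maps are exact inverses of the forward composition for any $\tau$,
including negative causal effects; the test suite verifies this at
machine precision.

### Where $\tau$ comes from

Two routes are supported.

1. **Internal, GREML-based.** If a set of SNPs can be classified as
   vertical-pleiotropy variants — affecting the outcome only through the
   exposure — a bivariate GREML fit on a GRM built from those SNPs alone
   gives $\mathrm{cov}(g_2, \beta_2)$ and $\mathrm{var}(\beta_2)$. Since
   the exposure and outcome effects of that set are independent by
   construction, $\tau = \mathrm{cov}(g_2, \beta_2)/\mathrm{var}(\beta_2)$
   (`estimateTau()`), with a delta-method standard error for the ratio.
2. **External.** Any Mendelian-randomization estimate can be wrapped with
   `causalEffect()` and used directly; no MR method is implemented here.

### Standard errors

Each corrected parameter is a smooth function $f(\theta)$ of the fitted
components, so $\mathrm{se}(f) = \sqrt{\nabla f' \,\Omega\, \nabla f}$
with $\Omega$ the components' sampling covariance — the 2×2 block over
$(\mathrm{cov}(g,\beta), \mathrm{var}(\beta))$ for the covariance
correction and the 3×3 block over
$(\mathrm{var}(g), \mathrm{var}(\beta), \mathrm{cov}(g,\beta))$ for the
variance and correlation corrections. $\Omega$ is taken from the inverse
average-information matrix of the REML fit (or the jackknife for summary
data). $\tau$ is treated as estimated without error by default, matching
the published form of the correction; `estimateTau()` still reports a
standard error for $\tau$ itself, and
`hvpCorrect(..., propagateTauSE = TRUE)` optionally adds an
independent-$\tau$ term through an extended gradient. The study-design
section below records why the error-free default remains well calibrated
in practice (making the extended form conservative).

## REML implementation

`fitUnivariateREML()` / `fitBivariateREML()` implement GREML with a
single relationship matrix. The bivariate model (trait-major stacking)
has covariance $G_0 \otimes A + R_0 \otimes I$; after rotating the data
onto the eigenvectors of $A$ the likelihood factors into $n$ independent
2×2 blocks $V_i = d_i G_0 + R_0$, making every iteration $O(n)$. The
algorithm runs three elementwise EM-style warm-up iterations and then
average-information (AI) updates with step-halving, so the restricted
log-likelihood never decreases across accepted iterations. Convergence
requires both the log-likelihood change and the largest component change
to fall below `tol = 1e-6`, within `maxit = 100` iterations. The
sampling covariance of the estimates is the inverse AI matrix at
convergence.

Numerical conventions:

* **Constraints.** The default is unconstrained (components may go
  slightly negative). The corrections are linear in the components, and
  truncating null components at zero would bias exactly the scenarios —
  complete mediation — where the corrected variance sits on the boundary.
  A `"boxed"` mode keeps variances non-negative and correlations inside
  the admissible region when estimates are wanted as parameters rather
  than inputs to the correction.
* **Degenerate inputs.** An identity-like GRM makes genetic and residual
  components jointly unidentifiable; the AI matrix is singular and the
  fit is returned flagged (`singular_information`, `converged = FALSE`)
  rather than erroring. A duplicated trait drives the genetic correlation
  to the boundary and is flagged `boundary`.
* **Undefined corrections.** When the corrected genetic variance is not
  positive the corrected correlation is undefined; the package returns
  `NA` with `rgDefined = FALSE` (and the command line exits with a
  dedicated code) instead of an imaginary number. A corrected variance
  within `1e-8` of zero is clamped to exactly zero for heritability
  reporting; more negative estimates pass through, so replicate means
  remain unbiased around zero.
* **Fixed effects.** Intercept only by default (phenotypes are assumed
  pre-adjusted to standardized residuals); an arbitrary covariate matrix
  is accepted.

## The simulation engine

`makeScenario()` encodes five generative settings used to validate the
correction, all with `var(eps) = 0.5` and the outcome's residual variance
set by the balancing formula
`var(e) = 1 - var(alpha) - tau^2 - 2 tau (cov(alpha,beta) + cov(e,eps))`
(the $\tau^2$ term carries the exposure's unit phenotypic variance), so
that `var(y) = 1` exactly:

1. vertical pleiotropy only (total genetic block `diag(0.5, 0.5)`);
2. vertical + horizontal pleiotropy
   (`G1 = [[0.35, 0.25], [0.25, 0.26]]`, `G2 = diag(0.15, 0.24)`;
   heritability 0.5 for both traits, horizontal-pleiotropy correlation 0.5);
3. scenario 2 plus residual covariance 0.1;
4. complete mediation (`var(alpha) = 0`, `var(beta) = 0.5`);
5. vertical + horizontal pleiotropy for the exposure, horizontal only for
   the outcome (`G1 = [[0.5, 0.25], [0.25, 0.26]]`, `G2 = diag(0, 0.24)`).

Genotypes are independent binomial(2, 0.2) dosages: 1000 SNPs carry the
horizontal-pleiotropy effects $(\alpha_1, \beta_1)$, drawn per SNP from a
bivariate normal with covariance `G1 / 1000` on standardized dosages, and
1000 vertical-pleiotropy SNPs are split half for the exposure effects
$\beta_2$ and half for the outcome effects $\alpha_2$, drawn
independently. Effects are placed on dosages standardized by the
generating allele frequency so aggregate variances match the blocks in
expectation. Scenarios 1 and 4 print a single genetic block; the split
across the two SNP sets is not separately specified and is taken as
half/half, to which every aggregate moment and the VP-set $\tau$
estimator are invariant. Binary traits are produced by liability
thresholding at a configured prevalence.

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent), minor-allele-frequency spectra, ascertained case-control
sampling, and misclassified variant sets (the vertical-pleiotropy SNPs
are known exactly). Passing recovery tests therefore demonstrates the
correctness of the estimators and corrections under the generative model,
not robustness to LD structure or to imperfect MR-based variant
classification.

## Study design and problem sizes

`runScenarioStudy()` runs replicate cohorts and the full pipeline
(genome-wide fit, VP-set fit, $\tau$, corrections). Replicates condition
on a single genotype draw by default: REML inference — including the
reported standard errors — is conditional on the realized relatedness
matrix, so redrawing only effects and residuals matches the estimand of
those standard errors while letting the two GRM eigendecompositions be
computed once per study. `reuseGenotypes = FALSE` redraws everything.

The packaged validation studies use n = 2000 individuals, 1000 + 1000
SNPs and 50 replicates per condition (100 for the confidence-interval
calibration), sizes at which the corrected estimates separate cleanly
from the uncorrected ones while a full study runs in about half a minute.
Monte-Carlo acceptance bands are three empirical standard errors of the
replicate mean.

A note on calibration: the delta-method standard error of the corrected
correlation ignores the sampling error of $\tau$, yet its 95% intervals
cover the generating value at close to the nominal rate in the packaged
studies. The genome-wide $\mathrm{cov}(g, \beta)$ and the VP-set $\tau$
are estimated from the same phenotypes, so their errors are positively
correlated and largely cancel in
$\mathrm{cov}(g,\beta) - \tau\,\mathrm{var}(\beta)$; the error-free-$\tau$
approximation is consequently less optimistic than it looks.

## Binary traits

Binary traits are fitted on the observed (0/1) scale with the linear
mixed model and transformed afterwards. For prevalence $k$, threshold
$t = -\Phi^{-1}(k)$ and density height $z = \phi(t)$
(`prevalenceContext()`):
proportion-of-variance parameters scale by $z^2/k(1-k)$, the genetic
covariance by $z_y z_c$, the genetic variance by $z_y^2$, and the causal
effect by $(z_y/z_c)\sqrt{\mathrm{var}(c)/\mathrm{var}(y)}$ with
observed-scale phenotypic variances ($k(1-k)$ for a 0/1 trait). A
quantitative member of a mixed pair contributes a factor of one, since
the kernels factorize per trait. The genetic correlation is invariant
under these maps. Sample prevalence is assumed to equal population
prevalence (no ascertainment correction); `liabilityVarComp()` transforms
a fitted object's genetic block (residual components have no liability
counterpart and are carried through flagged).

## Summary-statistics path

`correctSummary()` applies the identical arithmetic to a triple
(var(g), var(beta), cov(g, beta)) from a summary-level front end such as
LD score regression. Uncertainty comes either from a supplied 3×3
sampling covariance or from delete-one-block jackknife estimates of the
triple (200 blocks by convention, equal weights). The jackknife is
applied to each corrected quantity directly — rather than to the
components with a second delta step — which is exact for the linear
covariance correction and agrees with the delta method as the number of
blocks grows; the point corrections from the summary and individual-level
paths agree exactly on identical inputs. LDSC itself is not implemented;
its outputs are consumed.

## Worked example

```{r example, eval = FALSE}
cfg <- makeScenario(2, tau = 0.4, n = 2000)
cohort <- simulateCohort(cfg, seed = 42)
ph <- phenotypes(cohort)

fitGW <- fitBivariateREML(computeGRM(dosages(cohort, "all")), ph$y, ph$c)
fitVP <- estimateVPComponents(computeGRM(dosages(cohort, "vp")), ph$y, ph$c)
tauHat <- estimateTau(fitVP)
hvpCorrect(fitGW, tauHat)
```

The uncorrected fit reports a heritability near 0.78 and a genetic
correlation near 0.72 — the forward-composed biased values — while the
corrected estimates return to the generating 0.5 / 0.5.

## Limitations

* The causal-effect input is taken at face value; a biased MR estimate or
  a contaminated vertical-pleiotropy SNP set propagates into the
  corrections.
* Residual covariance is estimated but not decomposed further; no
  correction formula is defined for it.
* Single GRM only (no partitioned/multi-component models), two traits
  only, and no LD-aware simulation.
* The liability transforms assume no ascertainment (sample prevalence =
  population prevalence).
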