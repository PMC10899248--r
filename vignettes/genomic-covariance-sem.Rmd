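---
title: "Modelling genome-wide genetic covariance with gcsem"
author: "gcsem maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genome-wide genetic covariance with gcsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsem)
```

## The model

For $k$ standardized traits measured on $n$ unrelated individuals, `gcsem`
decomposes the phenotypic covariance into a genetic part, structured by the
genetic relationship matrix (GRM) $G$, and a residual part, structured by the
identity:

$$
\Sigma_V = \Lambda_A \Psi_A \Lambda_A^{\mathsf T} \otimes G +
           \Lambda_E \Psi_E \Lambda_E^{\mathsf T} \otimes I .
$$

$\Lambda_A$ ($k \times p_a$) and $\Lambda_E$ ($k \times p_e$) hold genetic
and residual factor loadings; the factor covariance matrices $\Psi_A$,
$\Psi_E$ are fixed to the identity throughout, so all structure lives in the
loading patterns and the model is a genetic confirmatory factor analysis.
Because phenotypes enter as Z scores (mean zero, unit variance), means are
not estimated. The stacked $nk$-dimensional observation vector is Gaussian,
and the whole likelihood factorizes after rotating the trait vectors into
the eigenbasis of $G$: with $G = U D U^{\mathsf T}$, rotated individual $i$
contributes a $k$-variate Gaussian with covariance
$d_i \Sigma_A + \Sigma_E$, where $\Sigma_A = \Lambda_A\Lambda_A^{\mathsf T}$
and $\Sigma_E = \Lambda_E\Lambda_E^{\mathsf T}$. A second, simultaneous
diagonalization of $(\Sigma_A, \Sigma_E)$ reduces every block to a diagonal
matrix, so one likelihood (or analytic gradient) evaluation costs
$O(nk^2)$ after a single $n \times n$ eigendecomposition of the GRM, which
is cached on the `grm` object. The test suite verifies exact equality of
this rotated likelihood with the dense Kronecker-product Gaussian density
on dozens of random instances — the rotation is an algebraic identity, not
an approximation.

Model families differ only in which loading cells are free:

* **Cholesky** — both parts lower-triangular and saturated;
  $k(k+1)$ free parameters. The descriptive reference model.
* **Independent pathway (IP)** — shared factor column(s) loading on all
  traits plus one specific factor per trait, in both parts.
* **IPC** — independent-pathway genetic part, saturated Cholesky residual
  part. The workhorse for data-driven genetic structure: hypotheses are
  imposed only where they are interpreted (the genetic part), while the
  residual covariance stays unrestricted.
* **Bi-factor** — an IPC-type genetic part plus one general factor loading
  on every trait; with $\Psi = I$ the general and grouping factors are
  orthogonal, which makes it the natural sensitivity check on the
  independence of IPC factors.

A specification with more free parameters than the $k(k+1)$ available
covariance moments is rejected at construction time. Latent factors also
need at least three indicator traits for a locally identified shared/
specific split; with only two, the likelihood is flat along a ridge and
loading estimates are arbitrary within it (the built-in three-factor
simulation scenario exists precisely because an earlier two-indicator
design exposed this).

## Estimation and uncertainty

Free loadings are estimated by quasi-Newton (BFGS) maximization with
analytic gradients, starting from Cholesky factors of half the phenotypic
covariance (saturated parts) or EFA-informed values (structured parts);
convergence is declared on relative likelihood change below $10^{-12}$
with a small gradient norm, after polishing restarts. Non-positive-definite
intermediate values return $-\infty$ so the line search retreats instead of
erroring. The likelihood is invariant to factor-column sign flips; fitted
solutions are canonicalized so each factor's first non-zero loading is
positive. Standard errors come from the inverse observed information
(central differences of the analytic gradient); Wald tests are reported on
the unstandardised scale.

The standardized solution rescales loadings to unit phenotypic variance and
derives SNP heritability $h^2_{SNP,t} = \Sigma_{A,tt}/\Sigma_{V,tt}$,
genetic correlations $r_g = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$
and factorial co-heritabilities $f^2_g = \sigma^2_{g_{jt}}/\sigma^2_{g_t}$
(the share of trait $t$'s genetic variance owned by factor $j$), each with
Delta-method standard errors propagated through a numerically differentiated
Jacobian. Standardized loadings exceeding one in magnitude are flagged as
Heywood-like rather than truncated. A parametric-bootstrap comparison in the
test suite confirms the Delta-method SEs to within 15%.

## GREML

`greml()` provides the univariate and bivariate variance-component baseline,
$y \sim N(0, \sigma^2_g G + \sigma^2_e I)$. Because prepared phenotypes are
exactly mean-zero, the default fit estimates no fixed effects, which makes
the univariate GREML objective identical to a one-trait Cholesky GRM-SEM fit
— the two agree to $10^{-4}$ in $h^2_{SNP}$ by construction, and the test
suite asserts it. The univariate optimizer profiles out the overall scale
and searches the heritability ratio on $[0,1)$ in one dimension, which is
deterministic, matches a dense grid-search oracle, and lands exactly on the
$\sigma^2_g = 0$ boundary when the data ask for it; evidence against zero
heritability uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. The bivariate fit (complete cases
over the trait pair) maximizes over the six covariance parameters with
closed-form vectorized 2×2 block inverses; $r_g$ is undefined and flagged
when a genetic variance collapses to the boundary. When covariates are
supplied, an intercept and covariates are projected out with the standard
REML correction instead.

`power_greml()` exposes the closed-form power of the heritability test:
$SE(\hat h^2) = \sqrt{2/(n^2 v)}$ with $v$ the GRM off-diagonal variance
(default $2\times10^{-5}$, typical of genome-wide common-variant GRMs in
unrelated European-ancestry samples), and a one-degree non-central
chi-square tail. At $h^2 = 0$ power equals the test size by construction.

## Phenotype preparation

Continuous traits go through fully-adjusted two-stage rank normalisation:
covariate residualization, rank-based inverse-normal transform, and a
second residualization so that the transform cannot re-introduce covariate
signal. The rank offset is Blom's 3/8 with average ranks for ties — the
procedure leaves the offset open, and this choice is declared rather than
inferred. Binary traits become deviance residuals of a covariate logistic
model; the signed square root of each observation's deviance contribution
preserves the direction of $y - \hat p$ and sums in square to the residual
deviance exactly. Standardization uses the population-SD convention
(denominator $n$), so standardized columns have exactly unit second moment;
this is stated here because sample-SD standardization would silently break
the unit-variance contract the likelihood relies on. Missing entries are
preserved; covariate fits use complete rows per trait, and the modelling
functions apply complete-case filtering across the modelled trait set
(matching a single reported sample size per model). Deviance residuals are
modelled directly; no liability-scale conversion is applied.

## The data-driven discovery pipeline

Given a saturated Cholesky fit, the pipeline proceeds:

1. **Factor count.** Eigendecomposition of the Cholesky-derived genetic
   correlation matrix; component $i$ is retained iff its eigenvalue exceeds
   1 (Kaiser) *and* exceeds the optimal-coordinate prediction — the value
   extrapolated at position $i$ by the line through eigenvalues $i+1$ and
   $k$ — with counting stopped at the first failure. The joint rule is a
   deliberate automatic surrogate for visual scree inspection; the
   conjunction and the stop-at-first-failure policy are design choices made
   here. The rule is conservative when leading eigenvalues are nearly
   equal, so shared factors of identical strength can be undercounted; the
   shipped three-factor scenario uses graded factor strengths, which is
   also the regime in which the rule is meant to operate.
2. **Genetic EFA.** The implied genetic covariance $\Sigma_A$ is factored
   by diagonally weighted least squares: minimize
   $\tfrac12\sum_l w_l^{-1}(s_l - \sigma_l(\theta))^2$ over the unique
   elements, with $w_l$ the Delta-method sampling variances of the
   $\Sigma_A$ entries (`va_sampling_variance()`); identity weights give
   ULS. Because the analysed matrix is itself an estimate, negative
   uniquenesses (Heywood cases) are flagged, not fatal. Varimax rotation
   comes from `stats`; oblique quartimin (oblimin) is implemented with the
   standard gradient-projection algorithm.
3. **Rotation choice.** Varimax is kept when the oblimin inter-factor
   correlations are ignorable ($|r| \le 0.32$, under 10% shared variance)
   or when the oblique solution offers the same zero/non-zero pattern at
   threshold 0.10 — i.e. no gain in simplicity. The pattern-similarity
   operationalization (thresholded-pattern agreement) is a design choice.
4. **IPC construction.** EFA loadings below 0.10 in magnitude become fixed
   zeros; surviving cells are freed with the EFA values as starting values;
   a post-fit trimming pass fixes specific genetic loadings with fitted
   standardized magnitude below 0.01 to zero and refits.
5. **Fit comparison.** `compare_models()` reports
   $AIC = -2\ell + 2\,N_{par}$, $BIC = -2\ell + N_{par}\log n_{ind}$
   (with $n_{ind}$ the number of modelled individuals) and nested LRTs;
   the best model is lowest AIC with BIC tie-break. Absolute fit uses the
   SRMR over the $k(k+1)/2$ unique standardized elements, with no
   degrees-of-freedom adjustment — the adjusted variant can be swapped in
   behind `srmr()` if one is ever pinned down.
6. **Mapping.** `extend_with_mapping()` loads one additional standardized
   measure (a polygenic score, a liability score) freely on every shared
   genetic factor, adds a specific factor for it and extends the residual
   Cholesky by one row, leaving the discovered structure constrained as
   found.

A phenotypic analogue (`phenotypic_pipeline()`) applies the same factor-count
rule to the phenotypic correlation matrix, runs a maximum-likelihood EFA on
one stratified half of the sample (halves matched on sex and missingness),
confirms the thresholded pattern by CFA on the other half (CFI > 0.95,
TLI > 0.95, RMSEA < 0.06), and refits on the full sample when confirmed;
any non-convergence is reported as a structured "empirically unidentified"
outcome rather than an error.

## The simulation harness

`sim_genotypes()` draws independent Hardy-Weinberg loci with uniform allele
frequencies in the requested range — no linkage disequilibrium, relatedness
or ascertainment structure, which bounds what passing recovery tests can
say about real cohort data (they validate the estimator under its own
assumptions, not robustness to their violation). `sim_scenario()` fixes a
generative path model in which every trait's squared loadings sum to one;
genetic factor scores are equal-weight sums of standardized causal dosages
over an equal partition of the loci, scaled to unit variance, so the true
$h^2$ of a trait is exactly its summed squared genetic loadings and the
true standardized loadings equal the path coefficients. Residual factor
scores are independent standard normals.

The shipped study conditions are 2000 individuals, 5000 causal loci and 20
replicates per scenario. Two six-trait scenarios ship with the package: two
shared genetic factors loading (0.65, 0.55, 0.45) on disjoint trait triples
with specific loadings of 0.30, without and with one cross-loading (trait 3
on factor 2 at 0.35). Where loading values were not pinned down externally,
they were fixed once inside the plausible 0.3–0.7 band with the stated
topology. `run_replicates()` redraws genotypes *and* phenotypes each
replicate from deterministically spawned child seeds, computes the GRM,
fits the model and collects standardized loadings with Delta-method SEs;
non-convergent replicates are flagged, excluded from summaries and counted.
`summarize_performance()` reports the median estimate, median bias,
empirical SE and 95%-interval coverage with Monte-Carlo SEs
($1.2533\,\mathrm{empSE}/\sqrt R$ for a median, $\mathrm{empSE}/\sqrt{2(R-1)}$,
and the binomial $\sqrt{c(1-c)/R}$).

The acceptance script runs both two-factor scenarios at the default 2000
individuals and 20 replicates with 1000 causal loci, and the three-factor
pipeline recovery at 2000 individuals and 1000 loci — locus counts chosen
so a replicate's GRM stays cheap while leaving the recovery properties
unchanged (the off-diagonal GRM variance only rescales estimation noise).
The unit-test suite exercises the same properties, plus smaller desk-scale
fixtures (800 individuals, 600 loci) for the module tests.

## Numerical choices and degenerate inputs

* GRM eigenvalues below $10^{-10}$ are clamped to zero; rank-deficient GRMs
  (fewer SNPs than individuals) are normal and handled silently, clearly
  negative eigenvalues warn.
* Monomorphic or zero-variance SNPs are excluded from GRM estimation with a
  message; an all-missing individual or an all-monomorphic panel errors.
* Relatedness pruning is greedy by descending count of above-cutoff
  partners (ties by input order): deterministic and scalable, and verified
  against exhaustive maximum-retained-set search on small instances, though
  not guaranteed optimal in general.
* `read_grm()` validates the `4\,n(n+1)/2` byte-length identity and ID
  counts before parsing; round-trips are exact at float32 precision.
* Constant traits, single-class binary traits, logistic separation and
  constant mapping variables are rejected with the offending trait named.

## Limitations

The generator omits linkage disequilibrium, relatedness, rare and de novo
variation, and ascertainment effects; estimates on real data inherit
whatever those processes do to the GRM. Bivariate GREML uses complete cases
rather than full-information blocks, trading a little efficiency for the
rotated-eigenbasis speedup. The factor-count rule undercounts equal-strength
factors by design. Liability-scale heritability conversion is out of scope,
as models operate on transformed scores directly.
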