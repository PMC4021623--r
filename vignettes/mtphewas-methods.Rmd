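---
title: "Methods: two-stage mitochondrial phenome-wide association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage mitochondrial phenome-wide association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mtphewas implements a two-stage strategy for asking whether mitochondrial
DNA variation contributes to many phenotypes at once:

1. **Polygenic prioritization.** For each phenotype, fit a mixed linear model
   with two genetic variance components -- one structured by a nuclear
   genetic relationship matrix (GRM), one by a mitochondrial allelic-sharing
   matrix -- and test the mitochondrial component with a boundary
   likelihood-ratio test. Phenotypes with evidence of an aggregate
   mitochondrial contribution are prioritized.
2. **Single-variant scan.** For every phenotype, regress the trait on each
   common mitochondrial variant (mtSNP) with covariate adjustment, and
   compare the count of nominally significant mtSNPs per trait with the count
   expected by chance. Agreement in ranking between the two stages is the
   framework's internal consistency check.

This vignette records the modeling choices and the numerical strategy. It is
shipped as source and is not pre-built.

## Relationship matrices

For diploid nuclear genotypes $x_{ij} \in \{0,1,2\}$ (counted A1 alleles for
variant $i$, sample $j$) with allele frequency $p_i$, the additive GRM is

$$A_{jk} = \frac{1}{m}\sum_{i=1}^{m}
  \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)},$$

with missing dosages mean-imputed and monomorphic variants excluded. Its
diagonal averages about 1 in an unstructured cohort.

Mitochondrial DNA is haploid, so an additive dosage model is not meaningful.
Instead the mitochondrial matrix is mean allelic sharing over
pairwise-complete haploid calls $x_{ij}\in\{0,1\}$:

$$S_{jk} = \frac{1}{m_{jk}} \sum_{i} \mathbf 1(x_{ij} = x_{ik}),$$

which is positive semidefinite (for complete data
$mS = XX' + (1-X)(1-X)'$), has unit diagonal and entries in $[0,1]$. Because
mitochondrial variation clusters into haplotype groups, $S$ is blocky, and
that block structure is what makes a small mitochondrial variance component
identifiable from as few as ~100 sites.

## The mixed model and EM-REML

For each trait, with covariates $X$ (intercept, age, sex, and the first two
nuclear principal components),

$$y = X\beta + g_{\mathrm{nuc}} + g_{\mathrm{mt}} + e, \qquad
g_{\mathrm{nuc}} \sim N(0, \sigma^2_{\mathrm{nuc}} A), \quad
g_{\mathrm{mt}} \sim N(0, \sigma^2_{\mathrm{mt}} S), \quad
e \sim N(0, \sigma^2_e I).$$

Variance components maximize the restricted likelihood

$$\ell_R(\sigma^2) = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
  \log|X'V^{-1}X| + y'Py\right],$$

via the expectation-maximization (EM) update
$\sigma_i^2 \leftarrow \sigma_i^2 + \sigma_i^4\,(y'PA_iPy -
\operatorname{tr}(A_iP))/n$. EM is used because every iterate stays
non-negative and the restricted likelihood never decreases -- exactly the
properties needed when the parameter of interest
($\sigma^2_{\mathrm{mt}}$) is often at or near zero. Binary traits are
analyzed on the observed 0/1 scale with the same linear model.

Two numerical choices matter in practice:

* **Rotated, low-rank likelihood evaluation.** All quantities are computed
  in the eigenbasis of the nuclear GRM, where its contribution to $V$ is
  diagonal; the mitochondrial matrix enters through its positive-eigenvalue
  factor and the Woodbury identity. One eigendecomposition is paid per GRM
  set (`reml_kernel()`), after which each likelihood evaluation costs
  $O(nr^2)$ for extra rank $r$ instead of $O(n^3)$. This is exact algebra,
  not an approximation; a dense Cholesky path is kept both as a fallback
  when $r$ is not small and as a transparent reference implementation.
* **Safeguarded SQUAREM acceleration.** At a boundary optimum the plain EM
  map converges at rate $1/t$ -- a null mitochondrial component can take
  $10^5$ iterations to flatten out. `fit_em_reml()` therefore wraps the EM
  map in squared extrapolation (two EM steps, one extrapolated candidate),
  accepting the candidate only if it does not decrease the restricted
  likelihood. Fixed points are unchanged, the recorded likelihood trace
  stays monotone, and boundary fits converge in a few hundred map
  evaluations. `accelerate = FALSE` restores the textbook iteration.

Standard errors come from the inverse average-information matrix at the
solution.

### PVE with contribution weights

The proportion of variance explained (PVE) by component $i$ is **not**
reported as $\sigma^2_i / \sum_j \sigma^2_j$: that convention silently
assumes each relationship matrix contributes $\sigma^2_i$ per unit of
phenotypic variance, which holds for a standardized GRM but fails badly for
the raw sharing matrix $S$, whose entries share a large common mean (two
random haplotypes agree at most sites). The variance of $y$ attributable to
component $i$, after projecting out the intercept, is $c_i\sigma^2_i$ with

$$c_i = \frac{\operatorname{tr}(A_i) - \mathbf 1'A_i\mathbf 1 / n}{n - 1},$$

($c = 1$ for the identity; $c \approx 1$ for a standardized GRM; $c \approx
0.28$ for a typical raw sharing matrix). mtphewas reports
$\mathrm{PVE}_i = c_i\sigma^2_i / \sum_j c_j\sigma^2_j$, which is invariant
to rescaling or recentering any relationship matrix, with delta-method
standard errors. Without this correction, mitochondrial PVE from a raw
sharing matrix is inflated several-fold.

## Boundary likelihood-ratio test

The null hypothesis $\sigma^2_{\mathrm{mt}} = 0$ lies on the boundary of the
parameter space, so the likelihood-ratio statistic
$\Lambda = \max(0,\; 2(\ell_{\mathrm{full}} - \ell_{\mathrm{reduced}}))$ is
asymptotically distributed as the equal mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, giving
$p = \tfrac12 P(\chi^2_1 \ge \Lambda)$ (a statistic of exactly zero has
$p = 0.5$). The plain $\chi^2_1$ p-value is reported alongside as the
conservative convention. `prioritize_phenotypes()` flags traits at
$p \le 0.05$ and marks a narrow "suggestive" band just above the threshold.

## Single-mtSNP scan and significance accounting

After excluding mtSNPs with minor allele frequency below 1%, each remaining
variant is tested per trait: ordinary least squares for continuous traits,
logistic regression for binary ones, both adjusted for age, sex and two
nuclear PCs, with haploid genotypes coded 0/1 (effects are per-allele).
Monomorphic variants and separated logistic fits are flagged untestable
rather than estimated.

No multiple-testing correction is applied; instead the per-trait count of
nominally significant mtSNPs is compared with the expected chance count
$m\alpha$ (for example, 86 tests at $\alpha = 0.05$ give 4.3). The Spearman
correlation between per-trait mitochondrial PVE and significant-mtSNP counts
summarizes the agreement of the two stages.

## Synthetic data with known architecture

`simulate_genotypes()` draws nuclear dosages as Binomial(2, $p$) with $p$
uniform on [0.05, 0.5], and mitochondrial haplotypes by assigning each
individual one of $h$ ancestral haplotypes and flipping each site at a small
mutation rate -- the haplotype mixture gives $S$ the block structure the
model needs. A configurable fraction of mitochondrial sites is ancestrally
monomorphic with a tiny flip rate, producing the sub-1%-MAF sites the filter
is meant to remove.

`simulate_phenotype()` draws genetic values as multivariate normal with
covariance proportional to the realized GRMs (through their symmetric square
roots, tiny negative eigenvalues clipped) and rescales each random part so
its in-sample variance matches its target share exactly; recovery tests
therefore have tight targets. Binary traits threshold the latent liability
at the empirical quantile of the configured prevalence. Every draw flows
from a single integer seed.

`make_paper_like_fixture()` bundles a desk-scale cohort -- 2000 samples,
5000 nuclear SNPs, 130 mtSNPs of which about a third are rare, eight
cardiometabolic-style traits with very small mitochondrial PVE -- as a
realistic end-to-end surface. Problem sizes throughout the test-suite and
examples (hundreds to a few thousand samples) are chosen so that everything
runs on one CPU in minutes; the algebra itself scales to tens of thousands
of samples via the kernel reuse described above.

## Limitations

* Binary traits are modeled on the observed scale; PVE for them is not a
  liability-scale heritability.
* The mixture LRT reference distribution is asymptotic in the information
  about $\sigma^2_{\mathrm{mt}}$. When the sharing matrix has very few
  haplotype blocks, the true null piles more than half its mass at zero and
  the test errs conservative (never anticonservative in our simulations);
  with many blocks the empirical null matches the ½--½ mixture closely.
* The association scan tests each mtSNP marginally; haplogroup, burden and
  joint tests are out of scope.
* The generator draws genetic values directly from the GRMs rather than
  from per-variant effect sizes, so it validates the variance-component
  machinery, not fine-mapping behavior.

## A minimal run

```r
library(mtphewas)

fx <- make_paper_like_fixture(seed = 1)
cfg <- run_config(traits = setNames(fx$config$traits$type,
                                    fx$config$traits$trait),
                  seed = 1)
res <- run_pipeline(cfg, genotypes = fx$genotypes,
                    phenotypes = fx$phenotypes)
render_summary(res)
autoplot(res)
```
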