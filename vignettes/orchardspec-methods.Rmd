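---
title: "Genomic mixed models for clonal seed orchards: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic mixed models for clonal seed orchards: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardspec)
```

## The problem

Clonal seed orchards replicate each genotype (a *clone*) as several grafted
trees (*ramets*) laid out on a row/column grid, often across more than one
site. Because the clones descend from plus trees selected in natural stands,
no pedigree is available; realized relatedness must instead be estimated
from genome-wide SNP markers. `orchardspec` implements the full quantitative
genetic workflow for such trials: marker quality control and a genomic
relationship matrix (GRM), needle functional trait (NFT) arithmetic and
hyperspectral preprocessing, REML fitting of genomic mixed models with
spatial residuals, and derived genetic parameters — broad-sense
heritability, type B (cross-site) genetic correlations, trait-pair and
year-to-year genetic correlations, and per-wavelength scans.

## The models

The univariate multi-site model for a trait measured on every ramet is

$$y = X\beta + Zu + e,$$

with fixed effects $\beta$ (overall mean, site, population-within-site),
clone effects $u \sim N(0, G)$ with

$$G = \begin{bmatrix} \sigma^2_{a,S1} & \sigma_{a,S1S2} \\
\sigma_{a,S1S2} & \sigma^2_{a,S2} \end{bmatrix} \otimes K,$$

where $K$ is the GRM, and residuals $e \sim N(0, R)$ that are
block-diagonal by site with a separable spatial structure plus an
independent nugget:

$$R_s = \sigma^2_{\xi,s}\, \mathrm{AR1}(\rho_{col}) \otimes
\mathrm{AR1}(\rho_{row}) + \sigma^2_{\eta,s} I.$$

The bivariate model for two traits (or the same trait in two years) on the
same clones replaces the site blocks by trait blocks:
$G = \Sigma_a \otimes K$ and $R = \Sigma_e \otimes I$, the residual
covariance applying only to co-observed ramets.

Derived quantities:

* broad-sense heritability
  $H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_\xi + \sigma^2_\eta)$,
* type B genetic correlation
  $r_B = \sigma_{a,S1S2} / \sqrt{\sigma^2_{a,S1}\sigma^2_{a,S2}}$,
* trait-pair / year-to-year genetic correlation, analogously from
  $\Sigma_a$.

The GRM uses the Yang et al. estimator: off-diagonals
$A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i) / (2p_i(1-p_i))$ and the
SNP-wise diagonal correction
$A_{jj} = 1 + m^{-1}\sum_i (x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2) /
(2p_i(1-p_i))$, with missing dosages mean-imputed to $2p_i$ inside the
computation only. Because $p_i$ is the *sample* frequency, the centered
marker matrix is orthogonal to the all-ones vector and the GRM has one
near-zero eigenvalue; `stabilize_psd()` adds a tiny documented ridge
(default `1e-6`) only when needed, and flags it.

## REML: parameterization, optimizer, uncertainty

All free parameters are transformed onto the real line: variances by log,
correlations and AR1 autocorrelations by `tanh`. The restricted
log-likelihood

$$\ell_R = -\tfrac12\left[\log|V| + \log|X^\top V^{-1}X| + y^\top P y +
(n-p)\log 2\pi\right]$$

is maximized with a quasi-Newton optimizer (`nlminb`) under box bounds,
with deterministic perturbed restarts if the first attempt fails to find a
positive-definite optimum. We chose this over classical average-information
updates because at orchard scale (hundreds of ramets) each likelihood
evaluation is cheap and a bounded quasi-Newton search is considerably more
robust near variance boundaries; the average-information matrix is still
computed — analytically at the optimum, with $\partial V/\partial\theta$
obtained by central differences — and its inverse supplies delta-method
standard errors, exactly as AI-REML software reports them.

Two structural accelerations keep desk-scale studies fast without any
approximation:

* AR1 powers are table lookups over precomputed integer lag matrices
  (occupied grid cells only, so mortality gaps simply become larger lags);
* balanced bivariate fits are evaluated in the eigenbasis of $ZKZ^\top$,
  where $V$ factors into independent 2×2 blocks; this is exactly equal to
  the dense evaluation (verified in the test suite to 1e-8) but linear in
  the number of ramets.

Two-site fits start from per-site univariate prefits plus the correlation
of shared-clone means; single-site fits start from half the clone-mean
variance (genetic), half the within-clone residual variance split between
spatial and nugget, and $\rho = 0.1$.

**Boundaries.** A variance estimate below $10^{-5}\,\mathrm{var}(y)$ or a
correlation beyond $|r| > 0.999$ is flagged as boundary-pinned. Correlations
on the boundary are reported with `NA` standard errors (the conventional
"0.99 (NA)" presentation). For heritability we treat a *non-genetic*
component pinned at zero as structurally absent — it is dropped from the
delta-method gradient rather than voiding the SE — because a collapsed
spatial component is a model simplification, not an inferential failure;
the SE is `NA` only when the genetic variance itself is pinned.

**Testing.** Genetic variances are tested by a likelihood ratio against the
no-genetics model using the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; genetic covariances against the
zero-covariance model using $\chi^2_1$. The mixture is the standard
reference for a single variance on its boundary; for the multi-site model
(where the null removes two variances and a covariance) it is a documented
simplification that errs conservative for the variance test.

## Scope decisions

* **Pooled heritability** is the ramet-count-weighted mean of per-site
  heritabilities from the joint fit. A constrained common-variance model is
  the alternative reading; weighting was chosen because it uses the joint
  fit unchanged and reduces to the single-site value when one site
  dominates.
* **Phenotypic variance** includes the spatially structured residual
  $\sigma^2_\xi$ as well as the nugget. Excluding spatial trend from
  $\sigma^2_p$ is exposed as an alternative by computing from the returned
  components directly.
* **Reflectance convention**: reflectance is computed as sample / white
  reference. The measurement-protocol phrasing of panel-ratio calibration
  is sometimes stated in the inverted order; the standard convention is the
  only one that yields values in $[0,1]$.
* **Canopy band preprocessing**: neighbor-pair averaging replaces band $i$
  by the mean of bands $(i, i+1)$ with the last band unchanged, then 13
  leading and 36 trailing bands are dropped; this is the only neighbor-pair
  scheme consistent with 269 − 13 − 36 = 220 analysis bands
  (429–919 nm).
* **Pigment equations**: the N,N-dimethylformamide coefficient set of
  Wellburn (1994), with the 750 nm absorbance treated as a turbidity blank.
  Negative blank-corrected absorbances are clipped to zero with a warning.
* **SNP filters**: call rate ≥ 0.90 and MAF ≥ 0.01 by default (typical
  array QC), HWE exact test at p ≥ 0.001, observed heterozygosity ≤ 60%
  pooled across clones. All four are configurable; the filter log reports
  first-failure and any-failure tallies per criterion.

## What the generator emulates

The synthetic orchard draws clone values from $N(0, \Sigma \otimes K)$ with
$K$ built from freshly simulated array-like SNPs (allele frequencies
Beta-distributed on (0.02, 0.5), optional Balding–Nichols population
structure), realizes the spatial field exactly through the covariance
square root of AR1 ⊗ AR1 on the full grid before subsetting to occupied
cells, and adds an independent nugget. Defaults chosen once for all
validation studies: phenotypic variance 1, spatial correlation 0.5 in both
directions, the non-genetic variance split equally between spatial field
and nugget, and (for bivariate year-pair studies) per-year heritability
0.25 with residual cross-year correlation 0.3 — magnitudes typical of
conifer needle traits and canopy reflectance bands. Spectra receive a
genetic signal that decays across bands through a Gaussian kernel in band
distance, so adjacent wavelengths share genetics and distant ones do not.

The generator does **not** emulate: linkage disequilibrium or sequence-level
structure, pedigree beyond optional half-sib-like population structure,
radiative-transfer realism in spectra (no PROSPECT-style physics),
measurement-device artifacts, or non-Gaussian trait distributions. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the model's own assumptions, not robustness to model
misspecification in field data.

## Validation studies and problem sizes

`recover_heritability_single()`, `recover_two_site()` and
`recover_trait_pair()` each generate one replicate study and analyze it
exactly as real data. The packaged validation suite runs 30 replicates per
scenario at the scales of the motivating designs — 31 clones / 200 ramets
and 29 clones / 148 ramets single-site, their two-site combination sharing
24 clones, and a 67-clone / 900-ramet bivariate year pair — with 5000 SNPs
per replicate. These sizes keep a full validation pass in minutes on one
CPU while leaving Monte-Carlo error on a 30-replicate mean near 0.01–0.02,
small against the recovery tolerances.

## Numerical notes and limitations

* Likelihood evaluations returning a non-positive-definite $V$ are treated
  as infeasible points (objective $10^{10}$), so the optimizer backs away
  rather than erroring.
* The AR1 correlation admits any integer coordinates; duplicate
  (site, row, col) cells are rejected.
* Ties in clonal rankings are broken by clone identifier for determinism.
* Fixed-effect design columns are reduced to full rank with a logged drop;
  population-within-site levels with a single observation are merged into
  a catch-all level.
* With ~30 clones, heritability estimates carry standard errors of
  0.07–0.10; single replicates scatter widely around truth and only
  replicate means are informative.
* The multi-site LRT mixture reference and the pooled-heritability
  weighting are documented simplifications (above); both are isolated
  behind small functions if alternatives are needed.
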