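---
title: "Comparing family-based and SNP-based heritability methods on socioeconomic indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing family-based and SNP-based heritability methods on socioeconomic indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Heritability estimates for socioeconomic status (SES) vary widely with the
indicator measured (educational attainment, occupational prestige, income,
wealth), the estimation design (twin/family models versus SNP-based models on
unrelated individuals), and the population. Registry-scale studies that
compare designs on one consistent population cannot share their
individual-level data, so independent verification has to run on synthetic
data whose generating parameters are known. `sesherit` implements both
halves: a simulator that produces extended pedigrees, gene-dropped genotypes
and multi-trait phenotypes with a known additive-genetic (A),
shared-environment (C) and non-shared (E) decomposition, and the four
estimator families that are standard in this literature, so that every
estimator can be validated by parameter recovery.

## Models

**Family-pedigree ACE.** For a relative pair with trait values $P_1, P_2$,

$$\mathrm{Var}(P) = a^2 + c^2 + e^2, \qquad
\mathrm{Cov}(P_1, P_2) = a^2 r_g + c^2 r_c,$$

with $r_g$ fixed by pedigree expectation (1 for MZ twins, 0.5 for full
siblings and DZ twins, 0.125 for first cousins) and $r_c$ the
environment-sharing correlation (1 within sibships; between first cousins
either assumed, or a free parameter $\rho_c \in [0,1]$). `fit_pair_ace()`
maximizes the product of bivariate-normal pair densities. Pairs are treated
as independent (a pseudo-likelihood): point estimates are consistent, but
because pairs within an extended family share members we provide family-level
cluster-robust (sandwich) standard errors via the `cluster` argument, and use
them whenever data come from the family simulator. The `rc_cousin = "free"`
model is identified as soon as three relationship classes with distinct
$(r_g, r_c)$ are present (e.g. MZ + sibling + cousin).
`sensitivity_sweep()` refits the model over a grid of assumed cousin
correlations (default step 0.05, hence 21 fits on $[0,1]$): assuming less
environment sharing than the generating value pushes the shared-environment
signal into $a^2$, which is the attenuation pattern the sweep is designed to
display.

**IBD sibling AE.** `estimate_ibd_sharing()` computes each sibling pair's
realised genome sharing $\hat r_g = 2\hat\phi$ with the KING-robust
within-family estimator
$\hat\phi = (N_{\text{both het}} - 2N_{\text{opp hom}})/(N_{\text{het},1} + N_{\text{het},2})$,
which requires no allele-frequency estimates and is invariant to allele
relabelling. `fit_ibd_ae()` then fits
$\mathrm{Cov}(P_1,P_2) = a^2 \hat r_g$, $\mathrm{Var}(P) = a^2 + e^2$.
Identification requires variation in realised sharing, so constant
$\hat r_g$ is refused with an explicit error. Because no C component is
modelled, shared environment (when present in the generating model) is
absorbed upward into $a^2$ — a property the tests assert rather than hide.

**GREML.** Genotypes are standardized columnwise to
$w = (x - 2p)/\sqrt{2p(1-p)}$ after a MAF cutoff (default 0.01), the genomic
relatedness matrix is $A = WW'/N$, close relatives are removed greedily above
a relatedness cutoff (default 0.025), and `fit_greml()` maximizes the
restricted likelihood of $y = X\beta + g + \varepsilon$ with
$\mathrm{Var}(y) = A\sigma_g^2 + I\sigma_\varepsilon^2$. We eigendecompose
$A$ once and rotate, which turns REML into a one-dimensional profile
optimization over $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_\varepsilon^2)$; the
SE comes from the observed information of $(\sigma_g^2, \sigma_\varepsilon^2)$
by the delta method. `fit_greml_biv()` extends this to two traits with
log-Cholesky-parameterized genetic and residual 2x2 covariance blocks and
reports $r_g = \sigma_{g,12}/\sqrt{\sigma_{g,1}^2\sigma_{g,2}^2}$.

**LD-score regression.** `run_gwas()` is an OLS per-SNP scan with covariates
projected out (with optional GRM-eigenvector PCs); its output records that
OLS stands in for a sparse-GRM mixed model, a deviation that matters only
when close relatives remain in the GWAS sample. `ld_scores()` computes
$\ell_j = \sum_{|k-j| \le w} r^2_{\text{adj}}(j,k)$ with the small-sample
adjustment $r^2_{\text{adj}} = r^2 - (1-r^2)/(n-2)$, the self pair included;
the window is defined in SNP positions (default 200) because the synthetic
map is block-based. `ldsc_h2()` regresses GWAS $\chi^2$ on $N\ell_j/M$ with
the standard iteratively-updated weights
$\propto 1/(\ell_j (1 + N h^2 \ell_j / M)^2)$; the slope is the SNP
heritability and the intercept the confounding term (1 under no
stratification). SEs are a delete-one block jackknife over contiguous SNP
blocks (default 200 blocks, standard practice). A negative fitted
heritability is reported as is, with a flag. `ldsc_rg()` regresses
$z_1 z_2$ on $\sqrt{N_1 N_2}\,\ell_j/M$ for the genetic covariance and
jackknifes the full correlation ratio.

## The synthetic cohort

`sim_pedigree()` builds extended families: a founder grandparent couple, a
brother and sister each mated to an unrelated founder, and one sibship per
couple, so the offspring generation contains full siblings, optional MZ/DZ
twin pairs, and first cousins across the two sibships. The offspring
generation is flagged as the phenotyped cohort (`cohort_ids()`), mirroring a
registry cohort observed in one generation; classification of relative pairs
(`classify_pairs()`) defaults to all individuals but takes an `ids` argument
to restrict to that cohort.

`sim_genotypes()` gene-drops biallelic SNPs: founder haplotypes are drawn
from population frequencies (uniform on 0.05–0.5), optionally with
within-block linkage disequilibrium through a Gaussian AR(1) copula, and
each transmission picks one grandparental origin per block of `block_len`
consecutive SNPs. Realised sibling sharing then varies around 0.5 with SD
$\approx \sqrt{\texttt{block\_len}/(8\,m)}$; the default `block_len = 100`
with 10,000 SNPs gives SD $\approx 0.035$, inside the plausible 0.02–0.06
range for genome-wide sharing. The KING estimator adds measurement noise of
SD $\approx 0.01$ at 10,000 SNPs, small relative to the true variation, so
attenuation of the IBD slope is mild. MZ twins receive identical genotypes.

`sim_phenotypes()` draws each family's trait vectors jointly from a
multivariate normal with covariance
$K \otimes S_A + Q \otimes S_C + I \otimes S_E$, where $K$ is the expected
relatedness matrix (MZ pairs set to 1), $Q$ the environment-sharing matrix
(1 within sibships, $\rho_c$ between cousins, 0 otherwise), and
$S_X = D_x^{1/2} R_X D_x^{1/2}$ combines per-trait variance fractions with
cross-trait correlation matrices. This Kronecker construction reproduces the
pairwise moments $a^2 r_g + c^2 r_c$ exactly, per trait and across traits.
In `snp_mode` the A part is instead built from the gene-dropped genotypes
($W\beta$ with normal effects scaled to the requested $a^2$ and correlated
across traits by $R_A$), which is required for the IBD, GREML and LDSC
designs to have a recoverable signal.

Generating defaults are the free-cousin-correlation decomposition of the
standardized indicators: $a^2 = 0.30$, $c^2 = 0.25$, $e^2 = 0.45$,
$\rho_c = 0.59$, a small male–female mean shift (0.1 SD), genetic cross-trait
correlations of 0.6, shared-environment correlations of 1 (a boundary the
estimators must tolerate), and non-shared correlations of 0.1.

`sim_registry_panel()` turns the latent traits into an 11-year yearly panel
from age 35: monetary indicators on a positive kroner-like scale with a
configurable fraction of zero/negative person-years, education as a
nondecreasing attainment series, occupation as a bounded prestige score.
`collapse_window()` reverses this the way registry analyses do — natural log
after setting non-positive monetary values to 1, then the mean over observed
years; the maximum for education — and `residualize_standardize()` z-scores
covariate-adjusted residuals before model fitting.

**Stratification scenario.** Two subpopulations with per-SNP frequency
shifts up to 0.05 (Fst of a few per mille, the within-continental-ancestry
scale) and a phenotypic offset of 0.5 SD between subpopulations. The offset
is deliberately strong: the drift realised in shifted frequencies itself
induces a random between-group trait difference of roughly 0.1 SD through
the genetic values, and the imposed offset must dominate it for the LDSC
intercept to detect confounding reliably.

## Numerical choices

- Variance components are parameterized on the log scale (softmax-free but
  equivalent in effect), so they are positive by construction; component
  correlations go through $\tanh$, keeping them inside $(-1, 1)$. Fits pinned
  near a boundary (a fraction below $10^{-3}$, or $\rho_c$ at 0 or 1) carry a
  `boundary` flag rather than being silently accepted — relevant because
  shared-environment cross-trait correlations sit exactly at 1 in the
  generating model.
- Standard errors are observed-information (numerical Hessian) with
  delta-method transformation to the standardized scale; confidence limits
  for variance fractions are clipped to $[0,1]$.
- The bivariate pair likelihood uses the sum/difference transform of the two
  members' trait vectors, which block-diagonalizes the 4x4 pair covariance
  into two 2x2 matrices; this keeps the likelihood closed-form and vectorized
  even when $r_g$ varies continuously across pairs (the IBD design).
- Pairwise component matrices need not be jointly consistent; before PCA a
  non-PSD matrix is projected by eigenvalue clipping and rescaling to unit
  diagonal, and the largest entry change is recorded on the object.
- Horn's parallel analysis uses the 95th-percentile rule; retention stops at
  the first component that fails. The component-matrix bootstrap is
  parametric by default (a Wishart draw of the sample covariance at the
  stated effective sample size, implied by sampling from the fitted
  multivariate normal), with observation resampling as an alternative mode;
  which resampling scheme the original procedure used is ambiguous, so both
  are provided. Percentile intervals of *sorted* eigenvalues are biased at
  eigenvalue ties — at the 4-variable identity the first explained-variance
  fraction concentrates above 25% — so coverage statements in the tests use
  a matrix with well-separated eigenvalues.
- `prune_relatives()` is greedy by degree with ties broken by sample order,
  which is deterministic and near-minimal; the selection rule of reference
  implementations is not specified publicly, so exact set equality is not a
  goal.

## What the tests show, and what they do not

The test suite checks exact values (pedigree kinship, PCA of canonical
matrices, the standardization formula), equivalences against independent
oracles (gene-dropping Monte Carlo for kinship, Falconer and
method-of-moments closed forms for ML, Haseman–Elston regression for REML),
invariances (allele flips, SNP permutations, seed determinism) and parameter
recovery at realistic design sizes: 20,000 sibling + 20,000 cousin + 2,000
twin pairs for the family ACE model, 10,000 sibling pairs with 10,000 SNPs
for the IBD design, n = 2,000 / m = 5,000 for GREML, and n = 5,000 /
m = 15,000–20,000 for LDSC. These sizes were chosen so each estimator's SE
is small enough for a 2-SE recovery check to be informative.

The synthetic genome is deliberately simpler than a real one: LD lives in
independent blocks with AR(1) decay rather than a recombination map with
long-range structure; allele frequencies are uniform rather than
U-shaped; there is no assortative mating, no indirect parental genetic
effects, no X chromosome, and no genotyping error. Passing recovery tests
therefore demonstrates that the estimators are correctly implemented and
identified under their own assumptions — not that those assumptions hold in
registry data. In particular, the IBD design's upward bias under unmodelled
shared environment, and the inflation of family-based estimates when the
cousin environment correlation is assumed to be zero, are reproduced as
properties of the models, exactly as the sensitivity analyses are meant to
display.

## Limitations

- Pair pseudo-likelihood: overlapping pairs are handled through sandwich
  SEs, not a joint family likelihood; likelihood-ratio tests across models
  should therefore be read informally.
- The OLS association scan is not a mixed model; with many close relatives
  in the GWAS sample the LDSC intercept will absorb the resulting cryptic
  relatedness.
- The bootstrap and permutation machinery defaults to 10,000 replicates as
  in common practice; examples and tests run smaller replicate counts, which
  only widens Monte-Carlo error on the interval endpoints.
- Four indicators bound the PCA: at most four components, and retention
  decisions are coarse.
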