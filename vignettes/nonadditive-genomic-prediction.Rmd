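---
title: "Genomic prediction with nonadditive effects: models, kernels and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with nonadditive effects: models, kernels and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pineGS)
```

## The problem

Forest tree breeding programs built on full-sib progeny testing estimate
breeding values from the resemblance between relatives. That resemblance
mixes additive variance with dominance and epistatic variance, and a
pedigree can only separate these sources when the mating design provides
the right contrasts. Marker-based (genomic) relationship matrices observe
the *realized* genome sharing of every pair of trees, which makes the
decomposition of the genetic variance into additive, dominance, and
first-order epistatic components far better conditioned than with a
pedigree alone — and it is this decomposition that decides whether clonal
deployment (which captures the total genetic value) is worth more than
seed-orchard deployment (which captures only the additive part).

`pineGS` implements that evaluation for a partial-diallel full-sib design
of the kind used in Scots pine breeding: 40 founder parents, 184
full-sib families, roughly 695 progeny, and a few thousand SNPs after
imputation and MAF filtering.

## Models

All models are univariate linear mixed models on environmentally adjusted
phenotypes, one record per tree, with the overall mean as the only fixed
effect. Writing $\mathbf{y} = \mathbf{1}\beta + \sum_k \mathbf{u}_k +
\boldsymbol\varepsilon$ with $\mathbf{u}_k \sim N(0, \mathbf{K}_k
\sigma^2_k)$ and $\boldsymbol\varepsilon \sim N(0, \mathbf{I}
\sigma^2_e)$, the model family is:

| label | random genetic effects | kernels |
|---|---|---|
| PBLUP-A | additive | $\mathbf{A}$ |
| PBLUP-AD | additive + dominance | $\mathbf{A}, \mathbf{D}$ |
| GBLUP-A | additive | $\mathbf{G}_A$ |
| GBLUP-AD | additive + dominance | $\mathbf{G}_A, \mathbf{G}_D$ |
| GBLUP-ADE | + three epistatic terms | $\mathbf{G}_A, \mathbf{G}_D, \mathbf{G}_{AA}, \mathbf{G}_{AD}, \mathbf{G}_{DD}$ |

Because the phenotypes are pre-adjusted to one record per tree, every
random-effect incidence matrix is the identity; the kernels carry all the
structure.

### Kernels

* **Pedigree additive** $\mathbf{A}$: tabular method in topological
  order, $A_{ii} = 1 + A_{gh}/2$, $A_{ij} = (A_{jg} + A_{jh})/2$ with
  $g, h$ the parents of $i$.
* **Pedigree dominance** $\mathbf{D}$: $D_{ij} = (A_{gk}A_{hl} +
  A_{gl}A_{hk})/4$ with $k, l$ the parents of $j$, $D_{ii} = 1$; pairs
  involving a founder get 0. This is the classical non-inbred formula; it
  is applied as-is when parents are related, with a warning (the designs
  targeted here have unrelated founders).
* **Genomic additive** $\mathbf{G}_A = \mathbf{Z}\mathbf{Z}' /
  2\sum_i p_i(1-p_i)$ with $\mathbf{Z} = \mathbf{M} - 2p_i$, where
  $\mathbf{M}$ counts alternative alleles (0/1/2) and $p_i$ is the
  in-sample alternative allele frequency.
* **Genomic dominance** $\mathbf{G}_D = \mathbf{W}\mathbf{W}' /
  \sum_i 4p_i^2q_i^2$, with $\mathbf{W}$ coding alternative homozygote,
  heterozygote and reference homozygote as $-2q_i^2$, $2p_iq_i$ and
  $-2p_i^2$.
* **Epistatic kernels** by Hadamard products, each rescaled to trace $n$:
  $\mathbf{G}_{AA} = (\mathbf{G}_A \odot \mathbf{G}_A) /
  (\mathrm{tr}(\mathbf{G}_A \odot \mathbf{G}_A)/n)$, and analogously for
  $\mathbf{G}_{AD}$ and $\mathbf{G}_{DD}$.

Allele frequencies are always estimated from exactly the individuals in
the loaded genotype matrix: in-sample frequencies are the convention of
the realized-relationship literature, and the choice of which individuals
(progeny only, or progeny plus parents) is the caller's, via the id list
handed to `kernel_set()`. Monomorphic loci are excluded before kernel
construction — their design columns are identically zero and they only
deflate the denominators — and the MAF ≥ 1% filter applied at load time
already removes them for realistic data.

Genomic kernels are rank-deficient whenever $n$ exceeds the number of
informative loci, so `ensure_psd()` adds the smallest diagonal ridge from
the ladder $10^{-6}, 10^{-5}, \dots, 10^{-2}$ that makes the smallest
eigenvalue comfortably positive, flags the matrix as adjusted, and
reports the ridge. A ridge perturbs the fitted components by at most its
own magnitude relative to the kernel scale (diagonals near 1), which is
negligible against the sampling noise of the variance components.

## REML

`fit_reml()` maximizes the restricted likelihood by average-information
(AI) updates with an EM first step and EM fallback, under the
non-negativity constraints:

* AI proposals are step-halved until the restricted log-likelihood does
  not decrease; components pushed negative are clamped to zero.
* A component below $10^{-8} \times \mathrm{var}(y)$ is fixed at zero and
  flagged — this mirrors how mixed-model software reports components
  "fixed at the boundary", and those flags are what the reports print as
  0 estimates with 0 standard error.
* The active set obeys the KKT conditions: a pinned component whose
  score (gradient) turns positive is released back into the free set, so
  the final solution is a genuine constrained optimum rather than an
  artifact of the iteration path.
* Convergence requires $|\Delta \log L| < 10^{-8}$ **and** a maximal
  relative parameter change below $10^{-6}$; non-convergence is a warning
  carrying the likelihood trajectory, and the estimates are still
  returned.

Approximate standard errors come from the inverse AI matrix at the
optimum; they are of delta-method quality only and are reported as such.
The AIC is $-2\log L + 2t$ with $t$ the number of variance parameters
*not* fixed at a boundary (residual included, fixed effects excluded
under REML); the alternative convention counting all parameters is
available via `aic_count = "all"`, since published tables rarely say
which one they use.

BLUPs and their prediction error variances come from the
projection-matrix identities
$\hat{\mathbf{u}}_k = \sigma^2_k \mathbf{K}_k \mathbf{P} \mathbf{y}$,
$\mathrm{PEV}_k = \sigma^2_k \mathbf{K}_k - \sigma^4_k \mathbf{K}_k
\mathbf{P} \mathbf{K}_k$, with cross-effect covariances
$-\sigma^2_k \sigma^2_l \mathbf{K}_k \mathbf{P} \mathbf{K}_l$ entering
the SEP of the total genetic value. These are algebraically the inverse
mixed-model-equation blocks; the test suite checks them against a
Gaussian-conditioning closed form.

### Identifiability

Two situations deserve explicit handling:

* A kernel numerically proportional to the identity cannot be separated
  from the residual; `fit_reml()` detects and warns about this
  confounding instead of returning an arbitrary split.
* In diallel designs with small families the dominance relationships are
  weak, so $\mathbf{G}_{DD}$ (their elementwise square) is nearly the
  identity, and $\mathbf{G}_{AD}$ is strongly correlated with
  $\mathbf{G}_{AA}$. The full five-kernel model therefore sits on flat
  likelihood ridges: single-fit estimates of the epistatic components
  have very large standard errors, and sums such as
  $\sigma^2_{dd} + \sigma^2_e$ are much better determined than the parts.
  This is a property of the design, visible equally in the enormous
  standard errors of published five-kernel fits; it is why the validation
  below looks at averages over replicates rather than single fits.

## Heritability, accuracy, selection

Narrow-sense heritability is $h^2 = \sigma^2_a/\sigma^2_p$ and
broad-sense $H^2 = \sigma^2_g/\sigma^2_p$, with $\sigma^2_g$ the sum of
exactly the genetic components the model fits (boundary-fixed components
contribute 0) and $\sigma^2_p = \sigma^2_g + \sigma^2_e$. Heritabilities
and variance fractions are kept at full precision and rounded to two
decimals only for reporting.

Predictive ability $r_1$ is the Pearson correlation between
cross-validated predictions and adjusted phenotypes; folds re-estimate
variance components on the training portion only, and validation
individuals are predicted purely through the relationship links
$\mathbf{K}[\mathrm{val}, \mathrm{train}]$. Predictive accuracy is
$r_2 = r_1/\sqrt{h^2}$ (or $/\sqrt{H^2}$ for total genetic values), with
the heritability taken from the full-data fit of the same model — one
heritability per trait and model, matching how such tables are reported.
The dispersion reported with $r_1$ is the SD across all replicate × fold
cells.

Selection response uses the top fraction of individuals ranked by their
predicted values expressed on the phenotype scale
($\hat\beta$ + BLUP): response percentages are ratios to the population
mean, so centered BLUPs would make them ill-defined — an interpretation
this package documents rather than attributes to any published
procedure. Per-year responses divide by the breeding-cycle length
(11 years for genomic selection, i.e. a 50% reduction of the 23-year
conventional cycle). Expected gain under truncation selection is the
breeder's-equation form $\Delta G\% = 100\, i\, h^2 \sigma_p/\bar{y}$
(broad-sense variant with $H^2$), with the intensity
$i = \phi(z_p)/p$ computed exactly from the normal density and quantile
($i = 2.67$ at $p = 0.01$).

## The synthetic-data generator

`simulate_dataset()` emulates the post-imputation state of a diallel
study. Defaults are the study conditions: 40 parents, 184 families
sampled without replacement from the 780 possible pairs, 695 progeny
allocated as evenly as possible (sizes 3 and 4), 6,344 unlinked loci with
founder alternative-allele frequencies uniform on [0.05, 0.95], and a
MAF floor of 0.01. Founder genotypes are drawn in Hardy–Weinberg
proportions; progeny genotypes are gene-dropped with fair Mendelian
transmission. Genetic values are drawn from the kernel-defined
multivariate normal laws ($\sigma^2_a \mathbf{G}_A$, etc., mutually
independent), so the GBLUP models are *correctly specified* for the
simulated data and parameter recovery is a well-posed test. The trait
mean defaults to 100 with a growth-trait-like architecture
$(\sigma^2_a, \sigma^2_{aa}, \sigma^2_e) = (300, 140, 1360)$.

What the generator deliberately does **not** emulate: linkage
disequilibrium beyond pedigree structure, genotyping error and
missingness, GBS read-depth artifacts, spatial field effects, or the
real (unknown) family-size distribution. Passing tests therefore
demonstrate the correctness of the estimators under the assumed model,
not robustness to these real-data features. A marker-effect route
(per-locus effects instead of kernel draws) would test robustness to
model misspecification; with unlinked loci and in-sample frequencies the
two constructions converge to the same covariance structure, so this
package ships only the kernel-based generator and treats marker-effect
simulation as out of scope.

Every `simulate_*` function seeds the RNG deterministically from
`config$seed` (with fixed offsets per stage), so standalone calls and
full-pipeline calls are equally bit-reproducible.

## Validation strategy and problem sizes

The test suite validates every construction against an independent
oracle: recursive coefficient-of-kinship recursion for $\mathbf{A}$,
direct formula evaluation for $\mathbf{D}$, hand computations and
double-loop Hadamard products for the genomic kernels, grid search over
the explicit restricted likelihood for REML (n ≤ 15), and
Gaussian-conditioning closed forms for BLUP/PEV (n ≤ 10).

Parameter recovery runs the full GBLUP-ADE model on 30 simulated
replicates at n = 695 and m = 2,000 loci (m reduced from the study's
6,344 — the kernels concentrate quickly in m, and 2,000 unlinked loci
already give kernel entries within a few percent of their large-m
limits). The check is that the replicate mean of each nonzero component
lies within two empirical standard errors — the SD of the estimator
across replicates — of the truth, that the true-zero dominance component
is boundary-flagged in a substantial fraction of replicates, and that
the ±2 SE intervals from the AI matrix cover the truth for at least 80%
of the free (non-boundary) estimates; boundary-pinned estimates carry no
AI standard error, so they are excluded from the interval check by
convention. Cross-validation integrity is checked by a masking audit
(poisoning validation phenotypes must not move their own predictions)
and by a null simulation whose mean $r_1$ must sit within three standard
errors of zero.

Published-table recomputations use the estimates shipped in
`reference_estimates()`: every printed heritability is reproduced from
its printed variance components to ±0.01, the quoted variance fractions
to the printed precision, and every reproducible printed predictive
accuracy from its $(r_1, h^2, H^2)$ inputs to ±0.02 (the slack reflects
the two-decimal rounding of the printed inputs; one printed $r_2$ entry
is internally inconsistent with every heritability printed for its
trait-model and is flagged as such in the tests rather than matched).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_loci = 2000, seed = 11)
dat <- simulate_dataset(cfg)
ids <- dat$phenotypes$id
ks <- kernel_set(ped = dat$pedigree, geno = dat$genotypes, ids = ids)
y <- setNames(dat$phenotypes$trait, ids)

fits <- lapply(c("PBLUP-A", "PBLUP-AD", "GBLUP-A", "GBLUP-AD",
                 "GBLUP-ADE"),
               function(m) fit_reml(y, ks, spec = model_spec(m)))
model_comparison(fits)
heritability(fits[[5]])

plan <- make_folds(ids, k = 10, replicates = 10, seed = 12)
cv <- cross_validate(y, ks, model_spec("GBLUP-A"), plan)
predictive_accuracy(cv$summary[["r1_add_mean"]],
                    heritability(fits[[3]])$h2)
```

## Known limitations

* The dominance relationship formula is the classical non-inbred one;
  inbred pedigrees get a warning, not a correction.
* Variance-component standard errors are asymptotic AI-matrix
  approximations and can be badly calibrated near boundaries.
* The five-kernel model is weakly identified under small-family diallel
  designs (see above); interpret single-fit epistatic components with
  their standard errors, not as point values.
* Individuals with exactly one recorded parent are rejected rather than
  half-founder coded; full-sib designs never produce them.
* No multi-trait models, spatial residuals, or Bayesian whole-genome
  regression.
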