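---
title: "Single-step SNPBLUP with breed-specific J-factors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step SNPBLUP with breed-specific J-factors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jfblup)
```

This vignette documents the statistical models implemented in `jfblup`, the
design decisions behind them, and what the synthetic populations used in the
test suite do and do not establish about real data.

## The evaluation model

The pedigree-based animal model for a trait recorded on crossbred animals is

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{u}_p +
  \mathbf{W}\mathbf{c} + \mathbf{e},$$

with one combined environmental factor (batch x pen x sex, coded as cell
means) in $\mathbf{b}$, additive genetic effects
$\mathbf{u}_p \sim \mathrm{MVN}(\mathbf{0}, \mathbf{A}\sigma^2_a)$ over all
pedigree animals, i.i.d. non-genetic maternal permanent environmental
effects $\mathbf{c} \sim \mathrm{MVN}(\mathbf{0}, \mathbf{I}\sigma^2_c)$
indexed by dam, and i.i.d. residuals. The single-step SNPBLUP model adds the
J-factor regression and replaces $\mathbf{A}$ by the combined relationship
matrix $\mathbf{H}$:

$$\mathbf{y} = \mathbf{X}\mathbf{b} +
  \mathbf{Z}\mathbf{J}\boldsymbol{\mu}_g + \mathbf{Z}\mathbf{u}_s +
  \mathbf{W}\mathbf{c} + \mathbf{e},$$

where for genotyped animals $\mathbf{u}_{s,g} = \mathbf{Z}_g\mathbf{g} +
\mathbf{a}_g$ decomposes into SNP effects and a residual polygenic part.
With $\mathbf{B} = \mathbf{I}\,(1-w)/(2\sum_o p_o(1-p_o))$ built from the
observed allele frequencies $p_o$ of the genotyped animals and
$\mathbf{G} = \mathbf{Z}_g \mathbf{B} \mathbf{Z}_g' + w\mathbf{A}_{gg}$,
the genotyped block of $\mathbf{H}$ is $\mathbf{G}$ and the ungenotyped
blocks follow by pedigree regression; equivalently
$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\mathrm{blockdiag}(\mathbf{0}, \mathbf{G}^{-1} - \mathbf{A}_{gg}^{-1})$.
Both constructions are implemented (`assemble_H()`) and must agree to
$10^{-6}$; the mixed-model equations use the inverse route
(`h_inverse()`), and the SNP-level parameterization (`solve_snp_level()`)
is kept as an exact cross-check of the $\mathbf{H}$-matrix solve rather
than a production path, since its system grows with the marker count.
Reported GEBV are $\mathbf{J}\hat{\boldsymbol{\mu}} + \hat{\mathbf{u}}_s$;
without a J-factor they are $\hat{\mathbf{u}}_s$.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w` | 0.05 | proportion of additive variance kept pedigree-distributed (residual polygenic); must be > 0 for `G` to be invertible |
| `var_a`, `var_c`, `var_e` | 69.01, 43.73, 151.07 | variance components in squared trait units (an early body-weight setting; heritability 0.26); they are inputs, not estimated |
| genotyping rate | 1, 0.75, 0.5, 0.25 | fraction of reference crossbreds whose genotypes are kept |
| scheme | `RND` / `TOP` | genotypes kept at random, or for the best own-phenotype animals (ties broken by a seeded shuffle, for determinism) |

Variance-component estimation (REML) is out of scope by design: components
enter through configuration, as they would from an upstream REML fit.

## J-factor covariates

`jfactor_direct()` implements
$\mathbf{J}_n = -\mathbf{A}_{ng}\mathbf{A}_{gg}^{-1}\mathbf{Q}$ with
$\mathbf{J}_g = -\mathbf{Q}$; the single-covariate case is
$\mathbf{Q} = \mathbf{1}$. Because each row of $\mathbf{Q}$ sums to one,
the multi-breed covariates row-sum to the single covariate — an identity
`jfactor_rowsum_check()` verifies, and the test suite asserts on every
pedigree it touches. The single covariate lies in $[-2, 0]$ and an
ungenotyped animal unrelated to every genotyped animal gets zeros. The
individual breed-specific columns respect the same bound under the
three-way-cross structures their fractions describe, but the bound is not
an algebraic guarantee per column: on arbitrary pedigrees the regression
of one breed's fraction can overshoot it slightly (the row sums never do,
since they collapse to the single covariate).

`jfactor_efficient()` restricts the dense solve to genotyped animals and
their ancestors. For any animal that is not an ancestor of a genotyped
animal, the tabular recursion makes its relationship row to the genotyped
set the average of its parents' rows, so its covariate is exactly the
parent average (unknown parents contributing zero rows); processing from
oldest to youngest therefore reproduces the direct formula, which the
suite checks to $10^{-8}$ across random pedigrees. This is an output
contract — the propagation is *defined* by its equality with the dense
formula, not by any particular implementation of it.

Three covariate constructions are supported:

- **ONE** — a single covariate, $\mathbf{Q} = \mathbf{1}$;
- **EXP** — pedigree-expected fractions: purebreds get unit rows and each
  non-founder the average of its parents' rows
  (`expected_breed_fractions()`), so a three-way A(BC) crossbred is
  0.5/0.25/0.25;
- **OBS** — genome-based observed fractions standardized by
  `scale_observed_fractions()`: the sire-breed column fixed at 0.5 (the
  exact paternal contribution), each dam-breed column multiplicatively
  rescaled so its crossbred mean is 0.25, then a per-animal rescale of the
  dam pair to 0.5. The mean correction is multiplicative rather than
  additive because it preserves non-negativity; the final pairwise step
  slightly perturbs the column means and they are deliberately not
  re-corrected, so the transformation is only *approximately* idempotent
  (differences around $10^{-4}$ on noisy input) while exact expected
  fractions are an exact fixed point. Purebred genotyped animals keep unit
  rows: their breed is known.

## Pedigree algebra

The numerator relationship matrix uses the recursive tabular method *with*
inbreeding, and unknown parents contribute nothing (one non-inbred,
unrelated base population; no genetic groups). Both choices were open:
breed means are carried by the J-factors here, which is exactly the role
genetic groups would otherwise play, and a valid $\mathbf{A}$ with
inbreeding is standard practice in the evaluations this package emulates.
All algebra is dense, sized for pedigrees up to roughly 20k animals; the
contract is tolerance-based (solve residuals $\le 10^{-10}$ against
$\mathbf{A}_{gg}$, $10^{-8}$ for the mixed-model equations), not
representation-based.

## Rank deficiencies

When every phenotyped animal is genotyped, the single J covariate is
constant at $-1$ over records and confounded with the general mean;
with expected fractions the two dam-breed columns are exactly collinear
whenever all genotyped crossbreds share the 0.25/0.25 expectation.
`solve_mme()` detects aliased fixed columns by QR, drops them (a
minimum-rank constrained solve), warns with the column names, and flags the
corresponding J coefficients as non-estimable; dropped covariates
contribute nothing to GEBV, which makes the J model at a 100% genotyping
rate *exactly* equal to the no-J model — a property the acceptance suite
asserts at $10^{-10}$. The scenario grid accordingly skips the no-J cell at
100% when the single-J cell is present.

## Validation statistics

Sire progeny means are raw records corrected by the fixed effects of a
sire model (cell means plus an i.i.d. sire effect at the variance ratio
implied by $h^2/4$), averaged per sire. The contract is behavioural —
corrected records are invariant to balanced fixed-effect shifts — rather
than tied to a specific software's output. Each mean is weighted by
Cameron's reliability
$\tfrac{1}{4}nh^2 / (1 + \tfrac{1}{4}(n-1)h^2)$, which is strictly
increasing in $n$ and $h^2$. Accuracy is the weighted Pearson correlation
between sire GEBV and progeny means, using weighted *central* moments (the
sums-of-products alternative without mean-centring was rejected: it is not
invariant to location shifts, which the statistics here must be);
dispersion is the weighted regression slope of progeny means on GEBV times
two, with expectation 1 for unbiased GEBV. Statistics are computed within
cross-validation folds, because the J-regressions differ between folds and
put GEBV on fold-specific scales. Report tables round half away from zero
to two decimals.

## The synthetic populations

`simulate_crossbred_population()` generates the design the analysis
assumes: three divergent purebred lines with Balding–Nichols
frequencies around uniform ancestral frequencies at a target mean pairwise
$F_{ST}$ of 0.24; a breed-A grandparent tier from which 161 sires descend
(the sib structure among sires is what keeps a validation sire estimable
once its own offspring are held out); F1 B x C dams; and one crossbred
generation hatched in 5 batches and 20 pens, each sire's offspring mostly
housed together, with near-equal sex ratios. Genotypes arrive by Mendelian
gene dropping with per-allele breed-of-origin tracking, so true breed
fractions are known; observed fractions add truncated normal noise
(SD 0.02, mimicking imperfect breed-of-origin assignment) before
standardization. The A sires are genotyped throughout; the maternal line is
not, so the single J covariate varies over phenotyped animals below a 100%
genotyping rate — the estimability structure the scenario grid requires.

True breeding values are SNP effects plus a pedigree-correlated residual
polygenic term ($w_{true} = 0.05$). SNP-effect variance is scaled by the
*crossbred-level* expected heterozygosity
$\sum_o [p_{A,o}(1-p_{A,o}) + \bar p_{BC,o}(1-\bar p_{BC,o})]$ rather than
$2\sum_o p(1-p)$ at pooled base frequencies: with divergent lines the
pooled-base denominator would understate the realized crossbred additive
variance by roughly $1 - 0.75\,F_{ST}$ (about 18% at $F_{ST}=0.24$), and
the variance components being emulated are crossbred-level estimates.
Defaults produce 1932 crossbreds and 2000 independent SNPs — the
population size at which the package's stochastic properties are tested
(10 simulation replicates, 5 folds of the 161 sires: four of 32 and one
of 33).

What the generator does **not** emulate: linkage disequilibrium beyond
drift (SNPs are independent, so absolute accuracy levels are not
comparable to chip data), founder selection history, multiple generations,
or genotyping error. Passing tests therefore establish internal
consistency of the estimator chain and the *direction* of
selective-genotyping effects, not the magnitudes a specific commercial
population would show.

## Numerical choices

- Dense Cholesky/QR throughout; mixed-model systems up to ~4k equations
  solve in seconds with an optimized BLAS.
- Identity checks (J equivalence, row sums, Q row sums) at $10^{-8}$ —
  double-precision dense solves at these sizes leave orders of magnitude
  of headroom.
- $w = 0$ is refused where $\mathbf{G}^{-1}$ is required; the $w = 1$
  limit short-circuits to pedigree BLUP with zero SNP effects.
- Monomorphic SNPs are retained with a warning (they contribute zeros);
  a fully monomorphic panel is an error.
- Seeds: one root seed per grid run; replicate, fold and selection seeds
  are derived deterministically from it, so identical configurations give
  byte-identical tables.

## Limitations

Multi-trait models, random J-regressions, genetic groups/metafounders,
sparse $\mathbf{A}^{-1}$ factorizations for million-animal pedigrees, and
breed-of-origin phasing itself are out of scope; observed fractions are
inputs (or simulated). Maternal effects are non-genetic only — with a true
maternal genetic component the evaluation model is misspecified, which is a
known source of bias that fitting breed-specific covariates does not
resolve.
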