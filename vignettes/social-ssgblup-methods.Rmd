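---
title: "Single-step genomic evaluation with social genetic effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with social genetic effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgeblup)
```

## The problem

Growth of group-housed pigs is not only a property of the individual:
each animal also affects the average daily gain (ADG) of its pen mates,
through competition for feed and space, aggression, tail biting, or
conversely calm and cooperative behaviour. The heritable part of that
influence is the *social genetic effect* (SGE, also called an indirect
genetic effect). Selection that ignores it can improve individual growth
while degrading group performance; selection on *total* breeding values
captures both routes.

`sgeblup` implements the full evaluation chain for this setting:
pedigree relationship machinery, genomic relationships and the tuned
single-step H matrix, REML estimation of the direct/social
(co)variances, breeding-value prediction with prediction-error-variance
(PEV) accuracies, forward cross-validation, and a pen-structured
simulator with known truth to test all of it.

## The models

For records `y` (ADG in g/d), the classical animal model is

    y = X b + Z_D a_D + W l + V g + e

and the social model adds the SGE term

    y = X b + Z_D a_D + Z_S a_S + W l + V g + e

* `b` — fixed effects: batch (a year-month-week contemporary-group
  class), sex, pen-size class, and age at target weight as a covariate.
* `a_D` — direct additive genetic effects on the animal's own phenotype.
* `a_S` — social genetic effects of each animal on every pen mate's
  phenotype. Row `i` of `Z_S` carries the dilution factor `d_g` (below)
  at the columns of animal `i`'s pen mates and zero on animal `i` itself.
* `l`, `g` — iid birth-litter and pen (group) environmental effects,
  `l ~ N(0, I sigma2_l)`, `g ~ N(0, I sigma2_g)`.
* `e` — iid residual.

The genetic effects are jointly multivariate normal,

    [a_D; a_S] ~ MVN(0, C (x) K),   C = [sigma2_aD  sigma_aDaS; sigma_aDaS  sigma2_aS]

where `(x)` is the Kronecker product and `K` is the relationship matrix:
the pedigree numerator matrix `A` for the pedigree variants, or the
single-step matrix `H` when genomic information enters. A positive
`sigma_aDaS` means fast growers also stimulate their pen mates' growth.

### Derived parameters

With `n` the average pen size over analysed records:

* total breeding value `TBV_i = a_D,i + (n - 1) a_S,i`;
* total heritable variance
  `sigma2_TBV = sigma2_aD + 2 (n - 1) sigma_aDaS + (n - 1)^2 sigma2_aS`;
* phenotypic variance
  `sigma2_P = sigma2_aD + (n - 1) sigma2_aS + sigma2_g + sigma2_l + sigma2_e`;
* total heritability `T2 = sigma2_TBV / sigma2_P`, which can exceed
  classical heritability and even 1 for large pens because the numerator
  grows quadratically in `n - 1`;
* direct-social correlation `r = sigma_aDaS / sqrt(sigma2_aD sigma2_aS)`.

The `(n - 1)^2` factor is why even a social variance two orders of
magnitude below the direct variance matters in pens of 5-10 animals.

### Dilution

Pens differ in size, and a social effect spread over many mates
contributes less per mate. The social incidences therefore carry
`d_g = sqrt((n_bar - 1) / (n_g - 1))` with `n_bar` the average pen size
(computed over the analysed records after the group-size filter) and
`n_g` the record's pen size; `d = 0` for an animal housed alone and
`d = 1` when dilution is disabled. This keeps the heritable social
variance comparable across pen sizes.

## Relationship matrices

* `build_A()` — dense numerator relationship matrix by the tabular
  method (desk-scale pedigrees).
* `compute_inbreeding()` — Meuwissen-Luo style computation of
  `F_i = A_ii - 1` without forming `A`; exact, `O(n * ancestors)`. The
  algorithm choice is ours; any exact method gives the same `F`.
* `build_A_inverse()` — Henderson's rules with inbreeding: animal `i`
  contributes `1/d_i` at `(i,i)`, `-0.5/d_i` at `(i, parent)` and
  `0.25/d_i` at parent pairs, with Mendelian-sampling variance
  `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F with one known parent, 1
  with none). Unknown parents are unrelated non-inbred founders; no
  unknown-parent groups are fitted.
* `build_A22()` — the pedigree relationship block of the genotyped
  animals, computed on the ancestor closure only.
* `build_G()` — VanRaden's method 1: `G = Z Z' / (2 sum p (1 - p))`
  with dosages centred by twice the allele frequency. Observed post-QC
  frequencies are used; whether a base-population frequency would be
  preferable is unknowable without base genotypes, and the observed
  frequency is the conventional single-step default. Missing dosages are
  mean-imputed to `2 p` after QC.
* `blend_G()` — `G_b = 0.95 G + 0.05 A22` by default, guaranteeing an
  invertible genomic matrix and retaining residual polygenic variance.
* `build_H_inverse()` — the single-step inverse: `A^-1` plus
  `tau G_b^-1 - omega A22^-1` on the genotyped block. `tau` scales the
  genomic relationships and is fixed at 1 in the default analysis;
  `omega` scales the pedigree block and is read as the proportion of
  polygenic variance not captured by markers. The analysis grid runs
  `omega` from 0.1 to 1.0 in steps of 0.1; values above 1 are excluded
  because the resulting H can lose positive definiteness.

### Genotype quality control

`qc_filter()` applies, in order: animal call rate >= 0.90, optional
non-autosomal removal, monomorphic removal, marker call rate >= 0.90,
minor allele frequency >= 0.01, and a 1-df Hardy-Weinberg chi-square
test at `p >= 1e-6`. These are conventional chip-QC defaults; every
threshold is a configuration knob, and the report lists counts removed
per rule in application order.

## REML estimation

`fit_reml()` maximises the restricted likelihood of the records-level
covariance

    V(theta) = sum_i theta_i S_i

with fixed structure matrices `S` (for example `S_aD = Z_D K Z_D'`) and
`theta = (sigma2_aD, sigma_aDaS, sigma2_aS, sigma2_g, sigma2_l,
sigma2_e)`. We work with the dense `n x n` matrix `V` rather than a
sparse factorization of the mixed-model equations: at the package's
intended scale (up to a few thousand records) dense Cholesky algebra is
faster, simpler, and exactly equivalent, and it gives the
average-information (AI) matrix and likelihood gradients directly.
Henderson's sparse mixed-model equations are still used for BLUP
solutions and PEV in `solve_mme()`, and the two routes are verified
against each other in the test suite.

The optimizer is AI-REML with three safeguards:

* a short EM-REML burn-in (3 iterations by default) that is monotone and
  picks a sensible basin of attraction;
* Levenberg-Marquardt damping of the AI step, with the damping constant
  persisting across iterations (shrinking on acceptance, growing on
  rejection), plus step-doubling along accepted directions — AI-REML
  otherwise zigzags on the flat likelihood ridges this model produces
  when litter, pen and social variances are weakly separated;
* projection to the admissible cone after every update: variances are
  floored at `1e-8 * var(y)` and the 2x2 genetic block is eigenvalue-
  clipped to positive semidefiniteness.

Iteration stops when the largest relative parameter change falls below
`tol` (default `1e-8`, `max_iter` 500) or when the restricted likelihood
has been stationary to about `1e-8` relative for three consecutive
iterations. The stall exit matters on ridge-shaped surfaces where
parameters keep drifting at numerically irrelevant likelihood gains; its
consequence is that independently started fits agree in logL to roughly
`1e-3`-`1e-5` rather than machine precision. Starting values default to
an equal split of the phenotypic variance across the variances with zero
covariance. Model comparison uses `AIC = -2 logL + 2 k` with `k` the
number of free (co)variance parameters (4 classical, 6 social);
fixed-effect counts are identical across compared models and cancel in
delta AIC.

`omega_grid()` fits `PED_classic`, `PED_social` and one single-step fit
per `omega`. The social fit is warm-started from the classical optimum
(so its likelihood can never fall below the nested model's), and each
`omega` fit is warm-started from its predecessor.

## Breeding values, accuracy, validation

`solve_mme()` returns BLUE/BLUP solutions and reads PEV off the diagonal
of the inverted MME coefficient matrix (selected columns are solved when
only a few animals are requested). Theoretical accuracy follows
`R_i = sqrt(1 - PEV_i / ((1 + F_i) sigma2))`, evaluated separately for
direct (`sigma2_aD`) and social (`sigma2_aS`) effects; numerical excess
of PEV is clipped to `R = 0` with a warning.

`forward_validation()` masks the phenotypes of the last `n_mask` birth
periods (default 2), fits or reuses training components, solves the
training MME (validation animals remain in the pedigree and, for
single-step variants, their genotypes remain in H — the genomic
preselection scenario), and correlates the validation animals' combined
breeding values `CBV_i = DBV_i + sum of pen mates' SBVs` with their
phenotypes corrected for fixed effects. Because batch is a time-composite
class, validation batches never occur in training; the correction
therefore applies the training estimates of the shared effects
(intercept, sex, pen-size class, age slope) and then centres the
remainder within validation batch, which is the contemporary-group
analogue of subtracting an inestimable batch effect. Corrected
phenotypes subtract fixed effects only, never litter or pen BLUPs.

## The simulator

`simulate_dataset()` generates a closed nucleus-herd-like population:

* discrete generations of full-sib litters (configurable size, default
  range 2-6 with mean near 4, matching typical performance-test family
  sizes) from dams mated once per generation to sires sampled with
  replacement;
* year-month-week-like batches within generation; single-sex pens of
  configurable size assembled within batch x sex after sorting litters,
  so pens contain 1-7 full sibs without modelling any particular farm
  allocation rule (real allocation rules are farm-specific and rarely
  recorded; this is a stand-in);
* breeding values drawn by a bivariate Mendelian-sampling recursion —
  animal effect = half the parental mean plus a deviation with
  per-animal variance `C * w_i`, `w_i = 0.5 - 0.25 (F_s + F_d)` — whose
  joint distribution is exactly `MVN(0, C (x) A)` while scaling linearly
  in pedigree size;
* unlinked biallelic markers gene-dropped through the pedigree from
  uniform founder frequencies (default in (0.1, 0.9));
* phenotypes `y_i = fixed + a_D,i + sum of pen mates' a_S + litter +
  pen + residual`, with ADG intercept 790 g/d, batch effects
  `N(0, 30^2)` g/d, a +40 g/d sex effect for males, small pen-size-class
  effects, and an age covariate `N(155, 10^2)` days with slope -2 g/d
  per day — magnitudes chosen to give realistic performance-test scale.

Default variance components (2320, 72, 23, 479, 256, 3739 in (g/d)^2 for
`aD, aDaS, aS, g, l, e`) are patterned on published social-model
estimates for Yorkshire growth, giving `T2` near 0.6 at pens of 5.

Two genetic architectures are available. The default draws breeding
values from the pedigree recursion: genotypes are then consistent with
`A` in expectation but carry no information beyond it, which isolates
pedigree-path behaviour. The `"markers"` architecture instead builds
breeding values from small additive effects at the gene-dropped markers
(bivariate effects scaled so founder-level variance matches `C`), so
genomic relationships carry real signal and single-step models can
genuinely outperform pedigree models — the scenario used for the
genomic model-selection study below.

What the simulator does *not* emulate: selection or overlapping
generations, linkage (markers are unlinked, so G lacks the long-range LD
structure of a real chip), genotyping-error patterns, non-genetic social
dynamics (dominance hierarchies), or heterogeneous residuals. Passing
tests on simulated data therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to the ways
real barn data violate them.

## Study designs used by the test suite

* **Oracle equivalences.** Sparse builders (`A^-1`, `A22`, the H block)
  and the MME solver are compared with independent dense oracles
  (recursive-kinship A, dense joint-equation inversion) on randomized
  pedigrees up to ~300 animals at `1e-8`.
* **Parameter recovery.** 20 replicates of ~1,000 phenotyped animals in
  pens of 5 (2,000 markers, 30% genotyped) under the default truth;
  `PED_social` is fitted to each. With constant pen size the social,
  litter and pen variances are only weakly separated — group-size
  variation is the strongest identifier of social variance — so
  replicate-level estimates of the small components scatter widely;
  the study checks the mean across replicates and the empirical 95%
  band. Problem sizes were chosen to make the full study run in minutes
  on a single core.
* **Model selection.** On the same recovery replicates, the social
  model's AIC is compared with the classical model's. Note the social
  signal in the default truth is small (`sigma2_aS` is 1% of the
  direct variance): at ~1,000 records the expected likelihood gain of
  the richer model is close to its 2-parameter AIC penalty, so AIC
  preference for the social model at this scale is genuinely borderline
  — published analyses with such components needed an order of
  magnitude more records for a clear preference. The single-step
  comparison uses the `"markers"` architecture with all phenotyped
  animals genotyped (ancestors ungenotyped) at ~570 records and a
  thinned omega grid {0.2, 0.6, 1.0}: the minimum-AIC single-step model
  is compared with `PED_social`, and the PEV-based accuracies of the
  genotyped animals under both.

## Numerical choices and edge cases

* Variance floors `1e-8 * var(y)`; eigenvalue clipping of `C` at
  `1e-8 * trace`.
* Animals housed alone keep their record with an all-zero social row
  (their direct information is retained); `keep_singleton_pens = FALSE`
  drops them instead.
* Records in pen-size classes holding <= 10% of records are dropped
  before analysis (`group_size_filter()`), and the dilution average
  `n_bar` is computed after that filter.
* `solve_mme()` clamps zero variance components to a tiny positive
  precision so degenerate limits (for example a vanishing genetic
  variance) remain solvable and shrink the corresponding effects to 0.
* All simulator randomness derives from one integer seed; regenerating
  with the same configuration is byte-identical.

## Known limitations

* REML point estimates on near-flat likelihood ridges (constant pen
  size, small social variance) are ill-determined in the data, and the
  stall-based convergence exit returns one point on the ridge; replicate
  scatter for those components is large.
* The dense records-level REML limits a single analysis to a few
  thousand phenotyped animals; the sparse-MME side (BLUP, PEV) scales
  further.
* No metafounders, unknown-parent groups, APY-style approximations of
  `G^-1`, multi-trait extensions beyond the 2x2 direct-social block, or
  Gibbs-sampling alternatives to REML.
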