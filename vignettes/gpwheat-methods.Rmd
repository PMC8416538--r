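---
title: "Models and methods behind gpwheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpwheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpwheat)
```

gpwheat implements the complete genomic-prediction workflow of a replicated
multi-environment breeding trial — the setting of a winter-wheat program
evaluating ~150 advanced and elite lines for several agronomic traits
(grain yield, protein, test weight, height, heading date) at five locations
with two complete blocks. This vignette explains the models, the priors and
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## Phenotype adjustment

Plot values are adjusted per environment with the randomized-complete-block
model

$$y_{ij} = \mu + R_i + G_j + e_{ij},$$

genotype fixed and replicate random, giving genotype BLUEs; a companion fit
with genotype random supplies REML variance components for the entry-mean
broad-sense heritability

$$H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / n_{Rep}}.$$

Across environments the model extends to environment, replicate-within-
environment and genotype-by-environment random effects, with genotype fixed
(BLUE) or random (BLUP). Balanced complete designs take an exact closed-form
path (block-adjusted line means); everything else goes through lme4, with
progressively simpler random structures as a fallback for degenerate data.
`reml_two_component()` is a self-contained EM-REML for the one-way
random-effects model (tolerance 1e-8, 10,000-iteration cap, components
floored at zero); it reproduces the balanced ANOVA closed form and agrees
with lme4 on unbalanced data, and exists so the heritability path has no
dependence on a particular mixed-model backend.

Prediction models consume per-environment BLUEs. Feeding across-environment
BLUPs instead is possible (`fit_across_env(..., mode = "blup")`) but is not
the default: the single-trait baseline is defined on within-environment
adjusted means, and using the same response everywhere keeps the model
comparison clean.

## Relationship matrices

`grm_vanraden()` builds $G = WW^\top / (2\sum_k p_k(1-p_k))$ with dosages
centered at twice the allele frequency estimated from the analyzed lines
themselves; `kinship_centered_ibs()` rescales $WW^\top$ so the mean diagonal
is 1. The two differ only by a scalar, which the variance components absorb
— prediction defaults to the VanRaden form. PSD repair clips eigenvalues
below 1e-8 and reconstructs, preserving eigenvectors because the REML and
Gibbs solvers work in G's eigenbasis. Markers are filtered at >20%
missingness and MAF < 0.05 (computed on non-missing calls, before
imputation), and unmapped markers can be dropped; missing dosages are then
replaced by the marker mean. Mean imputation preserves allele frequencies,
which is the only property the downstream matrices consume; haplotype-aware
imputation is out of scope and would mainly matter at much higher
missingness.

## Single-trait GBLUP

`fit_gblup()` maximizes the restricted likelihood of
$y = 1\mu + u + \varepsilon$, $u \sim N(0, G\sigma_g^2)$, over the variance
ratio after one eigendecomposition of the training block of $G$, with Brent
search on $\log\lambda$ bounded by $\delta = \sigma_e^2/\sigma_g^2 \in
[10^{-5}, 10^5]$. This is exactly ridge regression on centered markers at
penalty $\kappa = c\,\delta$ when $G = WW^\top/c$, and the test suite holds
the two paths to within 1e-6. Unphenotyped lines are predicted by
conditioning the joint normal on the training lines
($\hat u_{new} = \sigma_g^2 G_{new,tr} V^{-1}(y - \hat\mu)$), which equals
refitting with those lines included but costs nothing. Cross-validation
refits the variance components inside every repetition, so no information
leaks from test lines through hyperparameters.

## Bayesian multi-trait model

`fit_mt()` fits, per environment, $y_i = \mu + u_i + e_i$ with
$U \sim MN(0, G, \Sigma_t)$ (unstructured trait covariance) and diagonal
residual covariance. Full conditionals are conjugate throughout: in the
eigenbasis of $G$ the genetic values decouple into $n$ independent
$t \times t$ solves per sweep; $\Sigma_t$ is inverse-Wishart; residual
variances are scaled-inverse-$\chi^2$; missing cells are drawn from their
conditional normals (data augmentation), which is how CV1 (all traits of
test lines hidden) and CV2 (only the primary trait hidden) are fit without
special-casing. Priors are weakly informative and proper: flat intercepts,
$\Sigma_t \sim IW(t+2, I)$, residual scale at half the observed phenotypic
variance with 3 df. Production chains default to 5,000 burn-in / 25,000
iterations thinned by 5; the conjugate chains mix fast, and the automated
tests use 400–2,000 burn-in presets whose posterior means are
indistinguishable at test tolerances.

## Multi-trait multi-environment model (MTME)

`fit_mtme()` fits the environment-stacked model

$$Y = X\beta + Z_1 b_1 + Z_2 b_2 + \varepsilon,$$

with $b_1 \sim MN(0, G, \Sigma_t)$ genotype main effects,
$b_2 \sim MN(0, \Sigma_E \otimes G, \Sigma_t)$
genotype-by-environment-by-trait effects, and unstructured residual
covariance $R_e$ across traits within a plot row. The sampler never forms
$\Sigma_E \otimes G$ densely: transforming by the eigenvectors of $G$ and of
$\Sigma_E$ turns the $b_2$ update into $n\,l$ independent $t \times t$
solves. $\Sigma_t$ pools $b_1$ and $b_2$; $\Sigma_E$ has an inverse-Wishart
full conditional with scale
$\sum_{ab}(\Sigma_t^{-1})_{ab} M_a^\top G^{-1} M_b$; $R_e$ is
inverse-Wishart on the residuals. Priors: $\beta$ flat,
$\Sigma_t \sim IW(t+2, I)$, $\Sigma_E \sim IW(l+2, I)$,
$R_e \sim IW(t+2, I)$. $R_e$ is kept unstructured rather than diagonal: the
stacked model's residual is a within-row trait covariance and the general
form costs nothing here.

**Identifiability of the $\Sigma_E$/$\Sigma_t$ split.** Because $b_1$'s
covariance carries a fixed unit coefficient of $\Sigma_t$, the marginal
covariance of the data depends on $\Sigma_E$ and $\Sigma_t$ only through
$\Sigma_t \,(1 + \Sigma_{E,ef})$; a one-dimensional family of
$(\Sigma_t, \Sigma_E)$ pairs is likelihood-equivalent, and with exchangeable
environment correlations the inverse-Wishart prior drags the posterior mean
of the $\Sigma_E$ correlations well below the generative value while the
common signal migrates into $b_1$. The sampler therefore pins the
decomposition by rescaling $\Sigma_E$ to unit geometric-mean diagonal each
sweep and absorbing the scale into $\Sigma_t$ — a move that leaves the $b_2$
prior invariant and anchors the ridge at the point where the $b_1$ and $b_2$
scales are mutually consistent. With this convention the recovery tests find
environment correlations within about 0.1 of the generative 0.7 at $n=100$,
$l=3$; without it they sit 0.15–0.25 low.

Missing cells — held-out lines in cross-validation, held-out environments in
sparse testing — are augmented from the conditional normal of the missing
traits given the observed traits of the same row under $R_e$.

## Cross-validation schemes and sparse testing

All schemes draw repeated 80/20 line splits (`make_cv1_partitions()`;
a k-fold mode exists for the five-subpopulation reading of the design).
Predictive ability is the Pearson correlation between predictions and the
held-out lines' per-environment BLUEs — adjusted means, not raw plots, are
the observed phenotype throughout. Production repetition counts are 1,000
(single-trait), 50 (multi-trait) and 25 (MTME); the tests and the
acceptance script scale these down (20 / 6–8 / 2–8 repetitions) because the
comparisons they make are paired and the Monte Carlo error of a paired mean
difference is far smaller than of the means themselves. Summaries report
plain means by default with Fisher-z averaging as an option.

The sparse-testing experiment mirrors the allocation question a breeding
program faces: elite lines phenotyped everywhere, advanced lines in a
subset of environments, their remaining cells predicted by the MTME model
and scored against the held-out BLUEs. The no-information control
(block-diagonal $G$, $\Sigma_E = I$, no genotype main effect) verifies that
the measured accuracy comes from the modeled covariance paths and not from
leakage; because a single held-out correlation over a few hundred lines has
a null standard deviation near 0.07, the control's PA is measured as the
per-cell average over three independent truth replicates, putting the
near-zero claim at about 3.5 null standard deviations. Every scheme is
additionally audited by corrupting all masked cells before masking and
checking the fitted quantities are bit-identical.

## The synthetic-data generator

`simulate_genotypes()` draws marker allele frequencies from $U(0.05, 0.5)$,
gives each family four founder gametes, and builds each line by choosing two
gametes per 20-marker block — enough recombination structure to create the
elevated within-family kinship of a breeding panel without simulating
meiosis. `simulate_phenotypes()` then draws $b_1$ and $b_2$ from the MTME
generative model itself and adds environment means, block effects (sd
defaulting to half the genetic sd) and plot noise. The residual variance for
each (environment, trait) is set from the *realized* genetic variance so the
target entry-mean heritability is met exactly in truth, which is what makes
±0.08 recovery bounds on estimated $H^2$ honest at $n = 300$.

Default conditions mirror the emulated trial: 150 lines, 15 families, five
environments, two blocks, heritabilities in the 0.3–0.95 range, a
yield–protein genetic correlation of −0.54, and two season presets —
`season_low` (trait correlation 0.3, environment correlations 0.3) and
`season_high` (0.9 and 0.7) with a low-heritability primary trait (0.3) and
a strong secondary trait (0.7). The paper-style contrast that multivariate
models pay off most when trait and environment correlations are strong is a
property of these presets, and the tests verify it qualitatively (sign
tests over paired repetitions; majority over seeds), not as data-specific
magnitudes.

What the generator does *not* emulate: linkage disequilibrium beyond the
founder blocks, selection or drift across cycles, non-infinitesimal QTL
architectures, spatial field trend, and non-Gaussian trait distributions.
Passing recovery tests therefore demonstrate the estimators are correct
under the stated model, not that real GBS data meet its assumptions.

## Numerical choices and limitations

- G eigenvalues are floored at 1e-8 before entering any solver; REML delta
  is searched on $[10^{-5}, 10^5]$ and a boundary solution is reported as
  such (it occurs for phenotypes with no genomic signal).
- Gibbs draws are checked for finiteness each sweep; a non-finite draw
  aborts with the iteration index rather than contaminating summaries.
- All samplers use R's RNG (RcppArmadillo's R-RNG binding), so a single
  `set.seed()`/config seed reproduces chains exactly, across the samplers'
  R and C++ boundaries.
- Chain-length presets used by the automated checks: 2,000/8,000 for
  single-fit recovery checks, 400–1,000 burn-in inside repeated
  cross-validation loops; problem sizes are 50–300 lines, 500–1,000
  markers, 2–5 environments. These sizes were chosen so each check isolates
  one claim at comfortable Monte Carlo error.
- The MT model fixes diagonal residual covariance by design; correlated
  residuals within an environment belong to $R_e$ in the MTME model.
- Marker effects are equivalent-ridge only: no BayesA/B-style heavy-tailed
  marker priors, no dominance or epistatic kernels.
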