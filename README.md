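# gpwheat

Genomic prediction for replicated multi-environment breeding trials, the
setting of a winter-wheat program evaluating related advanced and elite
lines for several agronomic traits (yield, protein, test weight, height,
heading date) across locations with two complete blocks.

The package covers the whole workflow:

- **Marker QC and imputation** — missingness (> 20%) and MAF (< 0.05)
  filters, marker-mean imputation (`filter_markers()`, `impute_mean()`).
- **Relationship matrices** — VanRaden GRM
  `G = WW' / (2 Σ p(1−p))` and centered-IBS kinship (`grm_vanraden()`,
  `kinship_centered_ibs()`, `make_psd()`).
- **Adjusted means and heritability** — per-environment BLUEs from
  `y = μ + replicate + genotype + e`, across-environment BLUE/BLUP fits,
  EM-REML variance components, and entry-mean
  `H² = σg² / (σg² + σe²/nRep)`.
- **Single-trait GBLUP** — spectral REML for `y = 1μ + u + ε`,
  `u ~ N(0, G σg²)`, equivalent to ridge regression on centered markers
  (`fit_gblup()`).
- **Bayesian multi-trait model** — `U ~ MN(0, G, Σt)` with diagonal
  residual covariance, Gibbs-sampled with missing-phenotype augmentation
  (`fit_mt()`), enabling the CV1 and CV2 prediction schemes.
- **Multi-trait multi-environment model (MTME)** —
  `Y = Xβ + Z₁b₁ + Z₂b₂ + ε` with `b₁ ~ MN(0, G, Σt)`,
  `b₂ ~ MN(0, ΣE ⊗ G, Σt)` and unstructured residual covariance, sampled
  in the eigenbases of `G` and `ΣE` so the Kronecker covariance is never
  materialized (`fit_mtme()`).
- **Cross-validation and sparse testing** — repeated 80/20 schemes
  ST-CV1 / MT-CV1 / MT-CV2 / MTME-CV, predictive ability as the Pearson
  correlation between predictions and held-out BLUEs, percent-improvement
  summaries, and the sparse allocation design where advanced lines are
  phenotyped in a subset of environments and predicted in the rest
  (`run_st_cv1()`, `run_mt_cv()`, `run_mtme_cv()`,
  `run_sparse_experiment()`).
- **Synthetic breeding trials with known truth** — family-structured SNP
  panels and plot-level phenotypes drawn from the MTME generative model,
  with exact heritability calibration and serialized truth
  (`simulate_genotypes()`, `simulate_phenotypes()`,
  `make_paper_like_scenarios()`).

## Worked example

```r
library(gpwheat)

# a season_high-style trial: 150 lines, 5 environments, 2 traits
# (YLD h2 = 0.3, SEC h2 = 0.7, genetic correlation 0.9)
sc  <- make_paper_like_scenarios(seed = 3)$season_high
gen <- simulate_genotypes(sc)
sim <- simulate_phenotypes(gen, sc)

G <- make_psd(grm_vanraden(impute_mean(gen)))
b <- env_blues_table(sim$plots)            # per-env BLUEs + var components

heritability(attr(b, "varcomp")[["E1:YLD"]])
#> [1] 0.1464261

parts <- make_cv1_partitions(rownames(G), reps = 20, seed = 15)
st  <- run_st_cv1(b, G, traits = "YLD", partitions = parts)
cv2 <- run_mt_cv(b, G, traits = c("YLD", "SEC"), scheme = "cv2",
                 primary_trait = "YLD", partitions = parts,
                 cfg = gibbs_config(400, 1600, 4))
mean(st$pa);  mean(cv2$pa)
#> [1] 0.3626444
#> [1] 0.4502594
percent_improvement(mean(cv2$pa), mean(st$pa))
#> [1] 24.16001
```

The low-heritability yield trait is hard to predict from genotype alone
(ST-CV1 ≈ 0.36); borrowing the test lines' highly correlated,
high-heritability secondary trait (MT-CV2) lifts predictive ability to
≈ 0.45 — the core argument for multivariate genomic selection in a
breeding pipeline. `run_mtme_cv()` adds borrowing across correlated
environments, and `run_sparse_experiment()` turns it into a phenotyping
allocation design.

A config-driven pipeline (`pipeline_simulate()`, `pipeline_run()`, and the
`inst/scripts/gpwheat` wrapper) orchestrates QC → GRM → BLUEs → model fits
→ CV/sparse stages from a YAML file with a single seed and a manifest for
provenance.

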