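balanced_plots <- function(vals, lines = c("g1", "g2")) {
  plot_table(data.frame(line = rep(lines, each = 2), env = "e1",
                        rep = rep(c("r1", "r2"), 2), trait = "yld",
                        value = vals))
}

test_that("BLUEs equal line means on balanced complete data", {
  f <- fit_env_blues(balanced_plots(c(4, 6, 8, 10)), "e1", "yld")
  expect_equal(sort(f$blues$value), c(5, 9), tolerance = 1e-8)
  # single replicate: the BLUE is the observation
  p1 <- plot_table(data.frame(line = c("g1", "g2"), env = "e1", rep = "r1",
                              trait = "yld", value = c(3, 7)))
  f1 <- fit_env_blues(p1, "e1", "yld")
  expect_equal(sort(f1$blues$value), c(3, 7))
  # constant response: all BLUEs equal it, no genetic variance
  fc <- fit_env_blues(balanced_plots(rep(5, 4)), "e1", "yld")
  expect_equal(fc$blues$value, c(5, 5))
  expect_equal(fc$varcomp$sigma_g2, 0, tolerance = 1e-8)
})

test_that("larger panels: BLUEs track line means and H2 lands near target", {
  pan <- std_panel()
  f <- fit_env_blues(pan$sim$plots, "E1", "A")
  raw <- tapply(pan$sim$plots$value[pan$sim$plots$env == "E1"],
                pan$sim$plots$line[pan$sim$plots$env == "E1"], mean)
  expect_equal(f$blues$value[order(f$blues$line)],
               as.vector(raw[sort(f$blues$line)]), tolerance = 1e-6)
})

test_that("EM-REML reproduces the balanced ANOVA closed form", {
  v <- reml_two_component(c(1, 3, 5, 7), c("g1", "g1", "g2", "g2"))
  expect_equal(v$sigma_e2, 2, tolerance = 1e-4)
  expect_equal(v$sigma_g2, 7, tolerance = 1e-4)
  # identical within groups -> no residual variance
  v0 <- reml_two_component(c(2, 2, 9, 9), c("a", "a", "b", "b"))
  expect_equal(v0$sigma_e2, 0, tolerance = 1e-6)
  # all equal -> both components vanish
  vc <- reml_two_component(rep(4, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(vc$sigma_g2, 0)
  expect_equal(vc$sigma_e2, 0, tolerance = 1e-6)
  expect_error(reml_two_component(1:3, c("a", "b", "c")), "replication")
})

test_that("EM-REML agrees with lme4 on unbalanced data", {
  set.seed(8)
  sizes <- rep_len(c(2, 3, 1, 4), 12)
  grp <- rep(letters[1:12], times = sizes)
  y <- 10 + rep(rnorm(12, 0, 2), times = sizes) + rnorm(length(grp))
  v <- reml_two_component(y, grp)
  fit <- lme4::lmer(y ~ (1 | grp),
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(v$sigma_g2, vc$vcov[vc$grp == "grp"], tolerance = 1e-4)
  expect_equal(v$sigma_e2, vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
})

test_that("entry-mean heritability follows its closed form and monotonicity", {
  expect_equal(heritability(var_comp(7, 2, n_rep = 2)), 0.875)
  expect_equal(heritability(var_comp(3, 0, n_rep = 2)), 1)
  expect_equal(heritability(var_comp(0, 4, n_rep = 2)), 0)
  expect_warning(h <- heritability(var_comp(0, 0, n_rep = 2)))
  expect_true(is.na(h))
  h1 <- heritability(var_comp(2, 4, n_rep = 1))
  h2 <- heritability(var_comp(2, 4, n_rep = 4))
  h3 <- heritability(var_comp(5, 4, n_rep = 1))
  expect_lt(h1, h2); expect_lt(h1, h3)
})

test_that("realized heritability on synthetic data is close to target", {
  cfg <- sim_config(n_lines = 300, n_markers = 1000, n_families = 30,
                    n_envs = 2, traits = "A", h2 = 0.75, seed = 1)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  f <- fit_env_blues(sim$plots, "E1", "A")
  expect_lt(abs(heritability(f$varcomp) - 0.75), 0.08)
  expect_equal(unname(sim$truth$realized_h2["E1", "A"]), 0.75,
               tolerance = 1e-10)  # generator calibrates exactly
})

test_that("across-environment fits collapse to per-env answers when they should", {
  # same data duplicated in two environments
  one <- data.frame(line = rep(c("g1", "g2"), each = 2),
                    rep = rep(c("r1", "r2"), 2), trait = "yld",
                    value = c(4, 6, 8, 10))
  p <- plot_table(rbind(cbind(one, env = "e1"), cbind(one, env = "e2")))
  f <- fit_across_env(p, "yld", mode = "blue")
  expect_equal(sort(f$values$value), c(5, 9), tolerance = 1e-6)
  # no genetic variance -> BLUPs shrink fully to the grand mean
  pc <- plot_table(data.frame(line = rep(c("g1", "g2", "g3"), 4),
                              env = rep(c("e1", "e2"), each = 6),
                              rep = rep(rep(c("r1", "r2"), each = 3), 2),
                              trait = "yld", value = 7))
  fb <- fit_across_env(pc, "yld", mode = "blup")
  expect_equal(fb$values$value, rep(7, 3), tolerance = 1e-6)
  expect_error(fit_across_env(p, "absent"), "absent")
})

test_that("trait correlations behave for affine, inverted and independent traits", {
  set.seed(11)
  a <- rnorm(1000)
  b <- blue_table(data.frame(
    line = rep(sprintf("L%04d", 1:1000), 3), env = "e1",
    trait = rep(c("A", "B", "C"), each = 1000),
    value = c(a, 2 * a + 1, rnorm(1000))))
  cc <- trait_correlations(b)
  expect_equal(cc["A", "B"], 1)
  expect_lt(abs(cc["A", "C"]), 0.1)
  expect_equal(diag(cc), c(A = 1, B = 1, C = 1))
  b2 <- blue_table(data.frame(line = rep(c("x", "y", "z"), 2), env = "e1",
                              trait = rep(c("A", "B"), each = 3),
                              value = c(1, 2, 3, -1, -2, -3)))
  expect_equal(trait_correlations(b2)["A", "B"], -1)
})

test_that("environment correlations recover the simulated env structure", {
  SE <- matrix(0.7, 3, 3); diag(SE) <- 1
  cfg <- sim_config(n_lines = 500, n_markers = 600, n_families = 50,
                    n_envs = 3, traits = "A", h2 = 0.9,
                    Sigma_E_corr = SE, gxe_ratio = 4, seed = 6)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  # correlate the true per-env genetic values: dominated by the 0.7 GxE part
  b <- blue_table(do.call(rbind, lapply(names(sim$truth$genetic_value),
    function(e) data.frame(line = rownames(sim$truth$B1), env = e,
                           trait = "A",
                           value = sim$truth$genetic_value[[e]][, 1]))))
  cc <- env_correlations(b, "A")
  truth <- (1 + 4 * 0.7) / (1 + 4)   # main effect + correlated GxE share
  expect_lt(abs(mean(cc[upper.tri(cc)]) - truth), 0.1)
  # duplicated environment correlates perfectly
  b3 <- blue_table(data.frame(line = rep(letters[1:5], 2),
                              env = rep(c("e1", "e2"), each = 5),
                              trait = "A", value = rep(rnorm(5), 2)))
  expect_equal(env_correlations(b3, "A")["e1", "e2"], 1)
})

test_that("genetic correlations derive from the posterior trait covariance", {
  f <- structure(list(Sigma_t = diag(2)), class = "mt_fit")
  expect_equal(unclass(genetic_correlations_from_fit(f)), diag(2),
               ignore_attr = TRUE)
  f$Sigma_t <- matrix(c(4, 2, 2, 4), 2)
  expect_equal(genetic_correlations_from_fit(f)[1, 2], 0.5)
  f$Sigma_t <- diag(c(2, 5))
  expect_equal(genetic_correlations_from_fit(f)[1, 2], 0)
})

test_that("zero-variance traits yield NA correlations with a warning", {
  b <- blue_table(data.frame(line = rep(c("x", "y", "z"), 2), env = "e1",
                             trait = rep(c("A", "B"), each = 3),
                             value = c(1, 2, 3, 5, 5, 5)))
  expect_warning(cc <- trait_correlations(b), "zero-variance")
  expect_true(is.na(cc["A", "B"]))
})
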