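# two-trait panel with strong genetic correlation used in several blocks
rg_panel <- function() fixture("rg_panel", function() {
  St <- matrix(c(1, 0.8, 0.8, 1), 2)
  cfg <- sim_config(n_lines = 200, n_markers = 1000, n_families = 20,
                    n_envs = 2, traits = c("A", "B"), h2 = c(0.5, 0.7),
                    Sigma_t_corr = St, seed = 17)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  list(sim = sim, G = sim$G,
       Y = blue_matrix(env_blues_table(sim$plots), env = "E1",
                       trait = c("A", "B")))
})

test_that("gibbs_config guards its invariants", {
  cfg <- gibbs_config()
  expect_equal(cfg$n_burn, 5000L)
  expect_equal(cfg$n_iter, 25000L)
  expect_error(gibbs_config(n_iter = 50), "n_iter")
})

test_that("single-trait chain matches GBLUP in the conjugate limit", {
  pan <- std_panel()
  f <- fit_gblup(pan$y, pan$G)
  Y <- matrix(pan$y[rownames(pan$G)], ncol = 1,
              dimnames = list(rownames(pan$G), "A"))
  mt <- fit_mt(Y, pan$G, gibbs_config(2000, 8000, 5, seed = 1))
  expect_gte(stats::cor(mt$U[, 1], f$gebv), 0.98)
  # posterior variances bracket the REML point estimates
  sg_draws <- mt$Sigma_draws[, 1]
  se_draws <- mt$r_draws[, 1]
  mcse <- function(x) stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(sg_draws) - f$sigma_g2),
            3 * mcse(sg_draws) + 0.35 * f$sigma_g2)
  expect_lt(abs(mean(se_draws) - f$sigma_e2),
            3 * mcse(se_draws) + 0.35 * f$sigma_e2)
})

test_that("every retained covariance draw is PD and residuals positive", {
  pan <- rg_panel()
  mt <- fit_mt(pan$Y, pan$G, gibbs_config(200, 600, 3, seed = 2))
  for (k in seq_len(nrow(mt$Sigma_draws))) {
    S <- matrix(mt$Sigma_draws[k, ], 2, 2)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_true(all(mt$r_draws > 0))
  expect_true(all(is.finite(mt$U)))
})

test_that("the posterior genetic correlation recovers the simulated truth", {
  pan <- rg_panel()
  mt <- fit_mt(pan$Y, pan$G, gibbs_config(2000, 8000, 5, seed = 3))
  rg <- genetic_correlations_from_fit(mt)["A", "B"]
  expect_lt(abs(rg - 0.8), 0.15)
})

test_that("masked cells are augmented and predicted finitely", {
  pan <- rg_panel()
  Y <- pan$Y
  set.seed(5)
  masked_lines <- sample(rownames(Y), 40)
  Y[masked_lines, "A"] <- NA          # CV2-style mask
  Y[masked_lines[1:20], "B"] <- NA    # some lines fully masked (CV1-style)
  mt <- fit_mt(Y, pan$G, gibbs_config(500, 2000, 5, seed = 6))
  expect_false(anyNA(mt$U))
  pr <- predict_mt(mt, masked_lines, "A")
  expect_true(all(is.finite(pr)))
  expect_error(predict_mt(mt, masked_lines, "Z"), "unknown trait")
  expect_error(predict_mt(mt, "ghost", "A"), "ghost")
})

test_that("secondary-trait information lifts prediction of a masked primary", {
  # rg = 0.9, weak primary (h2 .3), strong secondary (h2 .7): keeping the
  # secondary phenotypes of test lines (CV2) must beat full masking (CV1)
  sc <- make_paper_like_scenarios(n_lines = 150, n_markers = 800,
                                  seed = 23)$season_high
  sim <- simulate_phenotypes(simulate_genotypes(sc), sc)
  Y <- blue_matrix(env_blues_table(sim$plots), env = "E1",
                   trait = c("YLD", "SEC"))
  G <- sim$G
  set.seed(7)
  wins <- 0; reps <- 6
  for (r in seq_len(reps)) {
    te <- sample(rownames(Y), 30)
    obs <- Y[te, "YLD"]
    Y1 <- Y; Y1[te, ] <- NA
    Y2 <- Y; Y2[te, "YLD"] <- NA
    cfg <- gibbs_config(500, 2000, 5, seed = 100 + r)
    pa1 <- predictive_ability(predict_mt(fit_mt(Y1, G, cfg), te, "YLD"), obs)
    pa2 <- predictive_ability(predict_mt(fit_mt(Y2, G, cfg), te, "YLD"), obs)
    wins <- wins + (pa2 > pa1)
  }
  expect_gte(wins, 5)
})

test_that("doubling the chain barely moves the posterior means", {
  pan <- std_panel()
  Y <- matrix(pan$y[rownames(pan$G)], ncol = 1,
              dimnames = list(rownames(pan$G), "A"))
  m1 <- fit_mt(Y, pan$G, gibbs_config(1000, 4000, 5, seed = 11))
  m2 <- fit_mt(Y, pan$G, gibbs_config(1000, 8000, 5, seed = 12))
  d <- abs(m1$U - m2$U)
  tol <- 2 * (m1$U_mcse + m2$U_mcse)
  # the stored MC errors ignore residual autocorrelation of the thinned
  # draws, so allow a small tail beyond the 2-sigma band
  expect_gte(mean(d < tol), 0.95)
  expect_true(all(d < 2 * tol))
})

test_that("chains are reproducible from the seed", {
  pan <- std_panel()
  Y <- matrix(pan$y[rownames(pan$G)], ncol = 1,
              dimnames = list(rownames(pan$G), "A"))
  m1 <- fit_mt(Y, pan$G, gibbs_config(200, 400, 2, seed = 9))
  m2 <- fit_mt(Y, pan$G, gibbs_config(200, 400, 2, seed = 9))
  expect_identical(m1$U, m2$U)
  expect_identical(m1$Sigma_draws, m2$Sigma_draws)
})

test_that("degenerate inputs are rejected with clear messages", {
  pan <- std_panel()
  Y <- matrix(pan$y[rownames(pan$G)], ncol = 1,
              dimnames = list(rownames(pan$G), "A"))
  Yc <- Y; Yc[] <- 2
  expect_error(fit_mt(Yc, pan$G), "variance")
  Ys <- Y[1:5, , drop = FALSE]
  expect_error(fit_mt(Ys, pan$G), ">= 10")
})
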