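test_that("CV1 partitions are disjoint, sized and reproducible", {
  ids <- sprintf("L%02d", 1:10)
  ps <- make_cv1_partitions(ids, reps = 3, seed = 42)
  expect_length(ps, 3L)
  for (p in ps) {
    expect_length(p$train_ids, 8L)
    expect_length(p$test_ids, 2L)
    expect_length(intersect(p$train_ids, p$test_ids), 0L)
    expect_setequal(c(p$train_ids, p$test_ids), ids)
  }
  ps2 <- make_cv1_partitions(ids, reps = 3, seed = 42)
  expect_identical(ps, ps2)
  expect_error(make_cv1_partitions(ids[1:4]), "n >= 10")
})

test_that("over many repetitions every line is tested about 20% of the time", {
  ids <- sprintf("L%03d", 1:100)
  ps <- make_cv1_partitions(ids, reps = 300, seed = 7)
  freq <- table(unlist(lapply(ps, `[[`, "test_ids"))) / 300
  expect_true(all(freq >= 0.13 & freq <= 0.27))
})

test_that("k-fold partitions cover each line exactly once as test", {
  ids <- sprintf("L%02d", 1:23)
  ps <- make_kfold_partitions(ids, k = 5, seed = 1)
  tested <- unlist(lapply(ps, `[[`, "test_ids"))
  expect_setequal(tested, ids)
  expect_length(tested, 23L)
})

test_that("predictive ability is the Pearson correlation, guarded", {
  expect_equal(predictive_ability(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(predictive_ability(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(round(predictive_ability(c(1, 2, 3, 4),
                                        c(1.1, 1.9, 3.2, 3.8)), 4),
               round(4.7 / sqrt(22.5), 4))   # = 0.9908
  expect_warning(pa <- predictive_ability(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(pa))
  # invariant under positive affine maps of the predictions
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(predictive_ability(2 * a + 5, b), predictive_ability(a, b))
})

test_that("percent improvement follows its formula", {
  expect_equal(percent_improvement(0.5, 0.4), 25)
  expect_equal(percent_improvement(0.4, 0.4), 0)
  expect_equal(round(percent_improvement(0.59, 0.36), 1), 63.9)
  expect_warning(pi0 <- percent_improvement(0.5, 0))
  expect_true(is.na(pi0))
})

test_that("single-trait CV1 returns the requested repetition structure", {
  pan <- std_panel()
  r <- run_st_cv1(pan$blues, pan$G, reps = 3, seed = 5)
  expect_s3_class(r, "cv_result")
  expect_equal(nrow(r), 3L * 2L)            # 3 reps x 2 envs x 1 trait
  expect_true(all(abs(r$pa) <= 1))
  s <- summary_cv(r)
  # stored summary means equal the arithmetic means of the per-rep values
  for (i in seq_len(nrow(s)))
    expect_identical(s$mean_pa[i],
                     mean(r$pa[r$env == s$env[i] & r$trait == s$trait[i]]))
})

test_that("pure-noise phenotypes give near-zero predictive ability", {
  pan <- std_panel()
  b <- pan$blues[pan$blues$env == "E1", ]
  set.seed(31)
  b$value <- rnorm(nrow(b))
  r <- run_st_cv1(blue_table(b), pan$G, reps = 40, seed = 8)
  expect_lt(abs(mean(r$pa)), 0.1)
})

test_that("a noiseless G-driven phenotype is predicted almost perfectly", {
  pan <- std_panel()
  ev <- eigen(unclass(pan$G), symmetric = TRUE)
  b <- data.frame(line = rownames(pan$G), env = "E1", trait = "A",
                  value = ev$vectors[, 1] * sqrt(ev$values[1]))
  r <- run_st_cv1(blue_table(b), pan$G, reps = 10, seed = 9)
  expect_gt(mean(r$pa), 0.9)
})

test_that("no CV scheme lets masked phenotypes reach the fitting stage", {
  # corrupting every masked cell must leave results bit-identical
  pan <- std_panel()
  b <- pan$blues
  parts <- make_cv1_partitions(intersect(unique(b$line), rownames(pan$G)),
                               reps = 2, seed = 77)
  corrupt <- function(b, bad_lines) {
    b$value[b$line %in% bad_lines] <- 1e6 * seq_len(sum(b$line %in% bad_lines))
    b
  }
  # ST-CV1: only the scoring differs, so compare the fitted GEBVs per rep
  for (p in parts) {
    d <- b[b$env == "E1", ]
    y <- stats::setNames(d$value, d$line)
    f1 <- fit_gblup(y[p$train_ids], pan$G)
    d2 <- corrupt(d, p$test_ids)
    y2 <- stats::setNames(d2$value, d2$line)
    f2 <- fit_gblup(y2[p$train_ids], pan$G)
    expect_identical(f1$gebv, f2$gebv)
  }
  # MT-CV1 and MT-CV2: corrupted masked cells never enter the sampler
  Y <- blue_matrix(b, env = "E1", trait = "A")
  Y <- cbind(Y, B = Y[, 1] + rnorm(nrow(Y)))
  te <- parts[[1]]$test_ids
  for (scheme in c("cv1", "cv2")) {
    Ym <- Y
    if (scheme == "cv1") Ym[te, ] <- NA else Ym[te, "A"] <- NA
    Yc <- Y
    Yc[te, if (scheme == "cv1") c("A", "B") else "A"] <- 9e9
    Ycm <- Yc
    if (scheme == "cv1") Ycm[te, ] <- NA else Ycm[te, "A"] <- NA
    cfg <- gibbs_config(100, 300, 1, seed = 3)
    expect_identical(fit_mt(Ym, pan$G, cfg)$U, fit_mt(Ycm, pan$G, cfg)$U)
  }
  # MTME: same argument at the design level
  spec <- build_mtme_design(b)
  hide <- spec$row_line %in% te
  s1 <- spec; s1$Y[hide, ] <- NA
  s2 <- spec; s2$Y[hide, ] <- 9e9; s2$Y[hide, ] <- NA
  cfg <- gibbs_config(100, 300, 1, seed = 4)
  expect_identical(fit_mtme(s1, pan$G, cfg)$B1, fit_mtme(s2, pan$G, cfg)$B1)
})

test_that("MT-CV2 beats MT-CV1 when the secondary trait is informative", {
  hp <- high_panel()
  parts <- make_cv1_partitions(rownames(hp$G), reps = 6, seed = 15)
  cfg <- gibbs_config(400, 1600, 4)
  cv1 <- run_mt_cv(hp$blues, hp$G, traits = c("YLD", "SEC"), envs = "E1",
                   scheme = "cv1", primary_trait = "YLD",
                   partitions = parts, cfg = cfg)
  cv2 <- run_mt_cv(hp$blues, hp$G, traits = c("YLD", "SEC"), envs = "E1",
                   scheme = "cv2", primary_trait = "YLD",
                   partitions = parts, cfg = cfg)
  expect_gt(mean(cv2$pa), mean(cv1$pa))
})

test_that("MTME CV produces one PA per repetition, environment and trait", {
  hp <- high_panel()
  r <- run_mtme_cv(hp$blues, hp$G, reps = 2, seed = 6,
                   cfg = gibbs_config(300, 900, 3))
  expect_equal(nrow(r), 2L * 5L * 2L)
  expect_true(all(is.finite(r$pa)))
})

test_that("sparse designs mask exactly advanced x held-out cells", {
  d <- build_sparse_design(sprintf("E%02d", 1:40), sprintf("A%03d", 1:110),
                           paste0("env", 1:5), paste0("env", 1:3))
  expect_equal(nrow(d$mask), 220L)
  expect_setequal(unique(d$mask$env), c("env4", "env5"))
  d1 <- build_sparse_design("e1", c("a1", "a2"), c("x", "y"), "x")
  expect_equal(nrow(d1$mask), 2L)
  expect_warning(d0 <- build_sparse_design("e1", character(), c("x", "y"), "x"))
  expect_equal(nrow(d0$mask), 0L)
  expect_error(build_sparse_design("e1", "a1", c("x", "y"), c("x", "y")),
               "held-out")
  expect_error(build_sparse_design("e1", "e1", c("x", "y"), "x"), "disjoint")
})

test_that("the sparse experiment predicts held-out environments usefully", {
  hp <- high_panel()
  ids <- rownames(hp$G)
  des <- build_sparse_design(ids[1:40], ids[41:150],
                             paste0("E", 1:5), paste0("E", 1:3))
  tab <- run_sparse_experiment(hp$blues, hp$G, des,
                               cfg = gibbs_config(500, 2000, 5, seed = 12))
  expect_setequal(unique(tab$env), c("E4", "E5"))
  expect_true(all(tab$pa > 0.1))
  expect_true(all(tab$n_lines == 110))
})

test_that("Fisher-z averaging changes only the aggregation, not the data", {
  r <- new_cv_result <- structure(
    data.frame(rep = 1:4, env = "e", trait = "t", model = "m",
               pa = c(0.2, 0.4, 0.6, 0.8)),
    class = c("cv_result", "data.frame"))
  s1 <- summary_cv(r); s2 <- summary_cv(r, fisher_z = TRUE)
  expect_equal(s1$mean_pa, 0.5)
  expect_equal(s2$mean_pa, tanh(mean(atanh(c(0.2, 0.4, 0.6, 0.8)))))
})
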