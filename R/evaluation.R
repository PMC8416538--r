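#' Random training/testing partitions (CV1-style)
#'
#' Draws `reps` independent 80/20 (by default) splits of the line panel.
#' Each repetition is an independent uniform draw, reproducible from
#' `seed`; a k-fold mode is available via [make_kfold_partitions()].
#'
#' @param line_ids character vector of line ids (n >= 10).
#' @param train_frac fraction of lines in the training set.
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return list of partitions, each a list(rep_index, train_ids, test_ids,
#'   seed).
#' @export
make_cv1_partitions <- function(line_ids, train_frac = 0.8, reps = 10,
                                seed = 1L) {
  n <- length(line_ids)
  stopifnot(n >= 10, train_frac > 0, train_frac < 1)
  n_train <- round(train_frac * n)
  if (n_train == 0 || n_train == n) stop("train or test set would be empty")
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    tr <- sample(line_ids, n_train)
    list(rep_index = r, train_ids = sort(tr),
         test_ids = sort(setdiff(line_ids, tr)), seed = seed)
  })
}

#' @rdname make_cv1_partitions
#' @param k number of folds.
#' @export
make_kfold_partitions <- function(line_ids, k = 5, seed = 1L) {
  n <- length(line_ids)
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  lapply(seq_len(k), function(f)
    list(rep_index = f, train_ids = sort(line_ids[fold != f]),
         test_ids = sort(line_ids[fold == f]), seed = seed))
}

#' Predictive ability
#'
#' Pearson correlation between predictions (GEBVs) and observed adjusted
#' phenotypes of held-out lines.
#'
#' @param pred,obs numeric vectors of equal length (>= 3 complete pairs).
#' @return correlation in \[-1, 1\], or `NA` with a warning if either
#'   vector has zero variance.
#' @export
predictive_ability <- function(pred, obs) {
  ok <- stats::complete.cases(pred, obs)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs; predictive ability undefined")
    return(NA_real_)
  }
  if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) {
    warning("zero variance in predictions or observations")
    return(NA_real_)
  }
  stats::cor(pred[ok], obs[ok])
}

#' Percent improvement over a baseline predictive ability
#'
#' 100 * (pa_model - pa_baseline) / pa_baseline.
#'
#' @param pa_model,pa_baseline predictive abilities; the baseline must be
#'   positive.
#' @return percent improvement, or `NA` with a warning.
#' @export
percent_improvement <- function(pa_model, pa_baseline) {
  if (is.na(pa_baseline) || pa_baseline <= 0) {
    warning("baseline predictive ability not positive; improvement undefined")
    return(NA_real_)
  }
  100 * (pa_model - pa_baseline) / pa_baseline
}

new_cv_result <- function(df, model) {
  df$model <- model
  class(df) <- c("cv_result", "data.frame")
  df
}

#' Summarize a cross-validation result
#'
#' @param r a `cv_result` (columns rep, env, trait, model, pa).
#' @param fisher_z average on the Fisher-z scale instead of the plain mean.
#' @return data.frame (env, trait, model, mean_pa, sd_pa, n_reps).
#' @export
summary_cv <- function(r, fisher_z = FALSE) {
  agg <- function(x) {
    if (fisher_z) tanh(mean(atanh(pmin(pmax(x, -0.999999), 0.999999)),
                            na.rm = TRUE))
    else mean(x, na.rm = TRUE)
  }
  out <- stats::aggregate(pa ~ env + trait + model, r, agg)
  names(out)[names(out) == "pa"] <- "mean_pa"
  sds <- stats::aggregate(pa ~ env + trait + model, r,
                          stats::sd, na.rm = TRUE)
  out$sd_pa <- sds$pa[match(paste(out$env, out$trait, out$model),
                            paste(sds$env, sds$trait, sds$model))]
  cnt <- stats::aggregate(pa ~ env + trait + model, r, length)
  out$n_reps <- cnt$pa[match(paste(out$env, out$trait, out$model),
                             paste(cnt$env, cnt$trait, cnt$model))]
  out
}

#' Single-trait GBLUP cross-validation (ST-CV1)
#'
#' For each repetition, environment and trait: fit [fit_gblup()] on the
#' training lines' BLUEs, predict the test lines through the relationship
#' matrix, and score predictive ability against the test lines' BLUEs.
#' Variance components are refit within every repetition (no leakage).
#'
#' @param b a [blue_table].
#' @param G relationship matrix.
#' @param traits,envs selections (default: all present).
#' @param reps repetitions (production default 1000; scale down freely).
#' @param seed integer seed.
#' @param partitions optional pre-built partitions (overrides reps/seed).
#' @return a `cv_result` data.frame (rep, env, trait, model, pa).
#' @export
run_st_cv1 <- function(b, G, traits = NULL, envs = NULL, reps = 1000,
                       seed = 1L, partitions = NULL) {
  if (is.null(traits)) traits <- unique(b$trait)
  if (is.null(envs)) envs <- unique(b$env)
  lines <- intersect(unique(b$line), rownames(G))
  if (is.null(partitions))
    partitions <- make_cv1_partitions(lines, reps = reps, seed = seed)
  rows <- list(); k <- 0
  for (p in partitions) for (e in envs) for (tr in traits) {
    d <- b[b$env == e & b$trait == tr, , drop = FALSE]
    y <- stats::setNames(d$value, d$line)
    pa <- tryCatch({
      f <- fit_gblup(y[intersect(names(y), p$train_ids)], G)
      te <- intersect(p$test_ids, names(y))
      predictive_ability(predict_st(f, te), y[te])
    }, error = function(err) {
      warning("rep ", p$rep_index, " (", e, ", ", tr, ") skipped: ",
              conditionMessage(err))
      NA_real_
    })
    k <- k + 1
    rows[[k]] <- data.frame(rep = p$rep_index, env = e, trait = tr, pa = pa)
  }
  new_cv_result(do.call(rbind, rows), "st_cv1")
}

#' Multi-trait cross-validation (MT-CV1 / MT-CV2)
#'
#' Per repetition and environment, the multi-trait model [fit_mt()] is fit
#' with test-line cells masked according to the scheme: CV1 masks all
#' traits of the test lines; CV2 masks only the primary trait, keeping the
#' test lines' secondary-trait phenotypes in the fit. Predictive ability is
#' scored on the primary trait over test lines.
#'
#' @param b a [blue_table].
#' @param G relationship matrix.
#' @param traits traits entering the model (>= 2).
#' @param envs environments (one MT model per environment).
#' @param scheme `"cv1"` or `"cv2"`.
#' @param primary_trait the trait scored (and masked under both schemes).
#' @param reps repetitions (production default 50).
#' @param seed integer seed.
#' @param cfg [gibbs_config] for the sampler.
#' @param partitions optional pre-built partitions.
#' @return a `cv_result`.
#' @export
run_mt_cv <- function(b, G, traits, envs = NULL, scheme = c("cv1", "cv2"),
                      primary_trait = traits[1], reps = 50, seed = 1L,
                      cfg = gibbs_config(2000, 8000), partitions = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(traits) >= 2 || scheme == "cv1")
  if (!primary_trait %in% traits) stop("primary_trait not among traits")
  if (is.null(envs)) envs <- unique(b$env)
  lines <- intersect(unique(b$line), rownames(G))
  if (is.null(partitions))
    partitions <- make_cv1_partitions(lines, reps = reps, seed = seed)
  rows <- list(); k <- 0
  for (p in partitions) for (e in envs) {
    Y <- blue_matrix(b, env = e, trait = traits)[, traits, drop = FALSE]
    Y <- Y[intersect(rownames(Y), lines), , drop = FALSE]
    te <- intersect(p$test_ids, rownames(Y))
    obs <- Y[te, primary_trait]                 # held out for scoring
    Ym <- Y
    if (scheme == "cv1") Ym[te, ] <- NA else Ym[te, primary_trait] <- NA
    pa <- tryCatch({
      cfg$seed <- (p$seed * 1000L + p$rep_index) %% .Machine$integer.max
      f <- fit_mt(Ym, G, cfg)
      predictive_ability(predict_mt(f, te, primary_trait), obs)
    }, error = function(err) {
      warning("rep ", p$rep_index, " (", e, ") skipped: ",
              conditionMessage(err))
      NA_real_
    })
    k <- k + 1
    rows[[k]] <- data.frame(rep = p$rep_index, env = e,
                            trait = primary_trait, pa = pa)
  }
  new_cv_result(do.call(rbind, rows), paste0("mt_", scheme))
}

#' Multi-trait multi-environment cross-validation
#'
#' Per repetition: an 80/20 line split; every cell of each test line is
#' masked in every environment and trait; [fit_mtme()] is fit on the
#' masked response and predictive ability scored per (environment, trait)
#' over the test lines against that environment's BLUEs.
#'
#' @inheritParams run_mt_cv
#' @param reps repetitions (production default 25).
#' @return a `cv_result` with one PA per (rep, env, trait).
#' @export
run_mtme_cv <- function(b, G, traits = NULL, envs = NULL, reps = 25,
                        seed = 1L, cfg = gibbs_config(2000, 8000),
                        partitions = NULL) {
  spec0 <- build_mtme_design(b, traits, envs)
  traits <- spec0$trait_names; envs <- spec0$env_ids
  lines <- intersect(spec0$line_ids, rownames(G))
  if (is.null(partitions))
    partitions <- make_cv1_partitions(lines, reps = reps, seed = seed)
  rows <- list(); k <- 0
  for (p in partitions) {
    spec <- spec0
    te_rows <- spec$row_line %in% p$test_ids
    obs <- spec$Y[te_rows, , drop = FALSE]
    spec$Y[te_rows, ] <- NA
    fit <- tryCatch({
      cfg$seed <- (p$seed * 1000L + p$rep_index) %% .Machine$integer.max
      fit_mtme(spec, G, cfg)
    }, error = function(err) {
      warning("rep ", p$rep_index, " skipped: ", conditionMessage(err))
      NULL
    })
    for (e in envs) for (tr in traits) {
      sel <- te_rows & spec$row_env == e
      pa <- if (is.null(fit)) NA_real_ else {
        cells <- data.frame(line = spec$row_line[sel], env = e, trait = tr)
        predictive_ability(predict_mtme(fit, cells)$prediction,
                           spec0$Y[sel, tr])
      }
      k <- k + 1
      rows[[k]] <- data.frame(rep = p$rep_index, env = e, trait = tr,
                              pa = pa)
    }
  }
  new_cv_result(do.call(rbind, rows), "mtme_cv")
}

#' Sparse-testing allocation design
#'
#' Elite lines are phenotyped in every environment; advanced lines only in
#' the training environments. The mask is the set of (advanced line,
#' held-out environment) cells hidden from fitting and later predicted.
#'
#' @param elite_ids,advanced_ids disjoint line sets.
#' @param envs all environments.
#' @param train_envs environments where advanced lines are phenotyped
#'   (a strict subset of `envs`).
#' @return list of class `sparse_design`.
#' @export
build_sparse_design <- function(elite_ids, advanced_ids, envs, train_envs) {
  if (length(intersect(elite_ids, advanced_ids)))
    stop("elite and advanced sets must be disjoint")
  if (!all(train_envs %in% envs)) stop("train_envs must be a subset of envs")
  test_envs <- setdiff(envs, train_envs)
  if (!length(test_envs)) stop("no held-out environments in the design")
  if (!length(advanced_ids)) warning("advanced set empty; mask is empty")
  mask <- expand.grid(line = advanced_ids, env = test_envs,
                      stringsAsFactors = FALSE)
  structure(list(elite_ids = elite_ids, advanced_ids = advanced_ids,
                 train_envs = train_envs, test_envs = test_envs,
                 mask = mask),
            class = "sparse_design")
}

#' Run a sparse-testing experiment
#'
#' Fits the MTME model with the design's masked cells hidden, predicts
#' them, and scores predictive ability per (held-out environment, trait)
#' over the advanced lines against their held-out BLUEs.
#'
#' @param b a [blue_table] containing observations for all unmasked cells
#'   (masked cells may be present; they are hidden before fitting and used
#'   only for scoring).
#' @param G relationship matrix.
#' @param design a [build_sparse_design()] result.
#' @param traits traits to model (default: all).
#' @param cfg [gibbs_config].
#' @return data.frame (env, trait, pa, n_lines) over the held-out cells,
#'   with the `mtme_fit` attached as attribute `fit`.
#' @export
run_sparse_experiment <- function(b, G, design, traits = NULL,
                                  cfg = gibbs_config(2000, 8000)) {
  spec <- build_mtme_design(b, traits)
  traits <- spec$trait_names
  masked <- spec$row_line %in% design$advanced_ids &
    spec$row_env %in% design$test_envs
  spec_obs <- spec                    # keep originals for scoring only
  spec$Y[masked, ] <- NA
  fit <- fit_mtme(spec, G, cfg)
  rows <- list(); k <- 0
  for (e in design$test_envs) for (tr in traits) {
    sel <- masked & spec_obs$row_env == e
    cells <- data.frame(line = spec_obs$row_line[sel], env = e, trait = tr)
    pa <- predictive_ability(predict_mtme(fit, cells)$prediction,
                             spec_obs$Y[sel, tr])
    k <- k + 1
    rows[[k]] <- data.frame(env = e, trait = tr, pa = pa,
                            n_lines = sum(sel))
  }
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}
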