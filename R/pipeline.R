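#' Validate a run configuration
#'
#' A run configuration is a flat YAML key tree driving the end-to-end
#' analysis: input paths (or a simulation block), trait/environment
#' selections, model choices, chain settings, CV scheme and repetitions, an
#' optional sparse-design block, output directory and the mandatory
#' top-level seed from which all randomness flows.
#'
#' @param cfg list (typically from `yaml::read_yaml()`).
#' @param stage `"simulate"` or `"run"` — which keys are required.
#' @return the validated config, invisibly; errors list all failures.
#' @export
validate_run_config <- function(cfg, stage = c("run", "simulate")) {
  stage <- match.arg(stage)
  problems <- character()
  need <- function(key) if (is.null(cfg[[key]]))
    problems <<- c(problems, paste0("missing key: ", key))
  need("seed"); need("outdir")
  if (stage == "run") {
    if (is.null(cfg$genotypes) && is.null(cfg$data_dir))
      problems <- c(problems, "need 'genotypes' (+ 'phenotypes') or 'data_dir'")
    for (p in c(cfg$genotypes, cfg$phenotypes))
      if (!is.null(p) && !file.exists(p))
        problems <- c(problems, paste0("file not found: ", p))
  }
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

run_manifest <- function(cfg, outdir) {
  manifest <- list(
    config_hash = sum(utils::head(utf8ToInt(paste(
      deparse(cfg[order(names(cfg))]), collapse = "")), 1e5) *
        (seq_len(min(1e5, nchar(paste(deparse(cfg[order(names(cfg))]),
                                      collapse = "")))) %% 97 + 1)),
    package_version = as.character(utils::packageVersion("gpwheat")),
    r_version = R.version.string,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}

#' Simulate a dataset from a config file
#'
#' Writes genotypes, phenotypes and truth to `outdir` per the config's
#' `simulate` block (or a named preset from
#' [make_paper_like_scenarios()]), along with a manifest JSON recording the
#' seed and versions. Re-running the same config reproduces the files
#' byte-identically.
#'
#' @param config path to a YAML config, or an already-parsed list.
#' @return invisibly, the output directory.
#' @export
pipeline_simulate <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_run_config(cfg, "simulate")
  sc <- if (!is.null(cfg$preset)) {
    pre <- make_paper_like_scenarios(seed = cfg$seed)
    if (!cfg$preset %in% names(pre)) stop("unknown preset: ", cfg$preset)
    pre[[cfg$preset]]
  } else {
    args <- cfg$simulate
    args$seed <- cfg$seed
    if (!is.null(args$Sigma_t_corr))
      args$Sigma_t_corr <- matrix(unlist(args$Sigma_t_corr),
                                  length(args$traits), byrow = TRUE)
    if (!is.null(args$Sigma_E_corr))
      args$Sigma_E_corr <- matrix(unlist(args$Sigma_E_corr),
                                  args$n_envs, byrow = TRUE)
    do.call(sim_config, args)
  }
  sim <- simulate_phenotypes(simulate_genotypes(sc), sc)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  write_sim_data(sim, cfg$outdir)
  run_manifest(cfg, cfg$outdir)
  invisible(cfg$outdir)
}

#' Run the configured analysis end to end
#'
#' Stages: marker QC and imputation, relationship matrix, per-environment
#' BLUEs with variance components and heritability, then the configured
#' model/CV stages (`st_cv1`, `mt_cv1`, `mt_cv2`, `mtme_cv`) and the
#' optional sparse-testing block. Every output carries the manifest hash
#' via the manifest JSON written alongside.
#'
#' @param config path to a YAML config, or an already-parsed list.
#' @return invisibly, a list with the summary table and file paths.
#' @export
pipeline_run <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(cfg$data_dir)) {
    cfg$genotypes <- file.path(cfg$data_dir, "genotypes.tsv")
    cfg$map <- file.path(cfg$data_dir, "marker_map.tsv")
    cfg$phenotypes <- file.path(cfg$data_dir, "phenotypes.tsv")
  }
  validate_run_config(cfg, "run")
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
    message(msg)
  }
  logf("stage qc: reading genotypes")
  g <- read_genotypes(cfg$genotypes, map_path = cfg$map)
  g <- filter_markers(g,
                      max_missing = cfg$max_missing %||% 0.20,
                      min_maf = cfg$min_maf %||% 0.05,
                      drop_unmapped = isTRUE(cfg$drop_unmapped %||% TRUE))
  jsonlite::write_json(attr(g, "filter_report"),
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE)
  g <- impute_mean(g)
  logf("stage grm: ", nrow(g$dosages), " lines x ", ncol(g$dosages),
       " markers")
  G <- make_psd(grm_vanraden(g))
  write_grm(G, file.path(outdir, "grm.tsv"),
            file.path(outdir, "grm.json"))
  logf("stage blues")
  p <- read_phenotypes(cfg$phenotypes)
  b <- env_blues_table(p)
  utils::write.table(b, file.path(outdir, "blues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  h2 <- lapply(attr(b, "varcomp"), function(v)
    list(sigma_g2 = v$sigma_g2, sigma_e2 = v$sigma_e2,
         H2 = suppressWarnings(heritability(v))))
  jsonlite::write_json(h2, file.path(outdir, "heritability.json"),
                       auto_unbox = TRUE, digits = NA)
  models <- cfg$models %||% list("st_cv1")
  reps <- cfg$reps %||% list()
  chain <- cfg$chain %||% list()
  cvcfg <- gibbs_config(chain$n_burn %||% 2000, chain$n_iter %||% 8000,
                        chain$thin %||% 5)
  results <- list()
  for (m in models) {
    logf("stage cv: ", m)
    results[[m]] <- switch(
      m,
      st_cv1 = run_st_cv1(b, G, reps = reps$st %||% 100, seed = cfg$seed),
      mt_cv1 = run_mt_cv(b, G, traits = unique(b$trait), scheme = "cv1",
                         primary_trait = cfg$primary_trait %||% unique(b$trait)[1],
                         reps = reps$mt %||% 10, seed = cfg$seed, cfg = cvcfg),
      mt_cv2 = run_mt_cv(b, G, traits = unique(b$trait), scheme = "cv2",
                         primary_trait = cfg$primary_trait %||% unique(b$trait)[1],
                         reps = reps$mt %||% 10, seed = cfg$seed, cfg = cvcfg),
      mtme_cv = run_mtme_cv(b, G, reps = reps$mtme %||% 5, seed = cfg$seed,
                            cfg = cvcfg),
      stop("unknown model: ", m))
  }
  all_cv <- do.call(rbind, results)
  if (!is.null(all_cv)) {
    utils::write.table(all_cv, file.path(outdir, "cv_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- do.call(rbind, lapply(results, summary_cv))
    base <- summ[summ$model == "st_cv1", ]
    if (nrow(base)) {
      idx <- match(paste(summ$env, summ$trait),
                   paste(base$env, base$trait))
      summ$pct_improvement_vs_st_cv1 <- ifelse(
        is.na(idx) | summ$model == "st_cv1", NA,
        suppressWarnings(mapply(percent_improvement, summ$mean_pa,
                                base$mean_pa[idx])))
    }
    utils::write.table(summ, file.path(outdir, "cv_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else summ <- NULL
  sparse_tab <- NULL
  if (!is.null(cfg$sparse)) {
    logf("stage sparse")
    des <- build_sparse_design(cfg$sparse$elite_ids, cfg$sparse$advanced_ids,
                               unique(b$env), cfg$sparse$train_envs)
    sparse_tab <- run_sparse_experiment(b, G, des, cfg = cvcfg)
    utils::write.table(sparse_tab, file.path(outdir, "sparse_pa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run_manifest(cfg, outdir)
  logf("done")
  invisible(list(summary = summ, sparse = sparse_tab, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
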