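#' Gibbs chain configuration
#'
#' Defaults follow the production settings used for multi-trait runs: 5,000
#' burn-in sweeps and 25,000 post-burn-in sweeps, thinned by 5. Reduced
#' presets are appropriate for cross-validation loops and tests; these
#' conjugate chains mix quickly.
#'
#' @param n_burn burn-in sweeps.
#' @param n_iter post-burn-in sweeps (>= 100).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed applied before the chain starts.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_burn = 5000, n_iter = 25000, thin = 5,
                         seed = NULL) {
  stopifnot(n_iter >= 100, n_burn >= 0, thin >= 1)
  structure(list(n_burn = as.integer(n_burn), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = seed),
            class = "gibbs_config")
}

#' Bayesian multi-trait genomic model
#'
#' Fits, for a set of lines measured on t traits (typically within one
#' environment), the multivariate model y_i = mu + u_i + e_i with genetic
#' values U ~ MN(0, G, Sigma_t) (unstructured trait covariance) and
#' independent residuals e_i ~ N(0, diag(R)) — the residual covariance is
#' fixed diagonal. The Gibbs sampler sweeps, in order: intercepts, genetic
#' values (in the eigenbasis of G), Sigma_t from its inverse-Wishart full
#' conditional, each residual variance from its scaled-inverse-chi-square
#' full conditional, and finally the missing phenotype cells from their
#' conditional normals (data augmentation) — so lines unphenotyped for some
#' or all traits are predicted directly (MT-CV1/MT-CV2).
#'
#' Priors: flat on intercepts; Sigma_t ~ IW(t + 2, I); each residual
#' variance ~ scaled-inv-chisq(3, half the observed phenotypic variance).
#'
#' @param Y numeric matrix, lines x traits, with rownames = line ids and
#'   colnames = trait names; `NA` cells are augmented. Alternatively a
#'   [blue_table] sliced via `env`/`traits`.
#' @param G relationship matrix (PSD; see [make_psd()]) covering all rows.
#' @param cfg a [gibbs_config].
#' @param env,traits used to slice `Y` when it is a `blue_table`.
#' @return list of class `mt_fit`: `U` (posterior-mean genetic values),
#'   `Sigma_t`, `R_diag`, `mu`, `U_mcse`, draw matrices and chain info.
#' @export
fit_mt <- function(Y, G, cfg = gibbs_config(), env = NULL, traits = NULL) {
  if (inherits(Y, "blue_table")) {
    stopifnot(!is.null(env))
    Y <- blue_matrix(Y, env = env, trait = traits)
  }
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y needs line ids as rownames")
  ids <- rownames(Y); tn <- colnames(Y)
  if (is.null(tn)) tn <- colnames(Y) <- paste0("T", seq_len(ncol(Y)))
  if (!all(ids %in% rownames(G))) stop("lines of Y missing from G")
  n_obs <- colSums(!is.na(Y))
  if (any(n_obs < 10))
    stop("each trait needs >= 10 observed lines; short: ",
         paste(tn[n_obs < 10], collapse = ", "))
  ovar <- apply(Y, 2, stats::var, na.rm = TRUE)
  if (any(ovar == 0))
    stop("zero observed variance for trait(s): ",
         paste(tn[ovar == 0], collapse = ", "))
  Gs <- unclass(G)[ids, ids]
  e <- eigen(Gs, symmetric = TRUE)
  if (min(e$values) < -1e-6) stop("G not PSD; run make_psd() first")
  d <- pmax(e$values, 1e-8)
  t <- ncol(Y)
  miss <- matrix(as.integer(is.na(Y)), nrow(Y), t)
  Y0 <- Y; Y0[is.na(Y0)] <- 0
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- .mt_gibbs(Y0, miss, e$vectors, d,
                   nu_sigma = t + 2, S_sigma = diag(t),
                   nu_r = 3, s2_r = ovar / 2,
                   n_burn = cfg$n_burn, n_iter = cfg$n_iter, thin = cfg$thin)
  k <- res$n_kept
  U <- res$U_mean; dimnames(U) <- list(ids, tn)
  Sigma_t <- matrix(colMeans(res$Sigma_draws), t, t, dimnames = list(tn, tn))
  structure(list(
    U = U, Sigma_t = Sigma_t,
    R_diag = stats::setNames(colMeans(res$r_draws), tn),
    mu = stats::setNames(colMeans(res$mu_draws), tn),
    U_mcse = res$U_sd / sqrt(k),
    Sigma_draws = res$Sigma_draws, r_draws = res$r_draws,
    mu_draws = res$mu_draws,
    observed = !is.na(Y),
    chain = list(n_burn = cfg$n_burn, n_iter = cfg$n_iter, thin = cfg$thin,
                 n_kept = k)),
    class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat("mt_fit:", nrow(x$U), "lines x", ncol(x$U), "traits;",
      x$chain$n_kept, "retained draws\n")
  cat("posterior-mean genetic correlations:\n")
  print(round(stats::cov2cor(x$Sigma_t), 3))
  invisible(x)
}

#' Predictions from a multi-trait fit
#'
#' @param f an `mt_fit`.
#' @param line_ids lines to predict.
#' @param trait trait name.
#' @return named vector mu_trait + U\[line, trait\].
#' @export
predict_mt <- function(f, line_ids, trait) {
  if (!trait %in% colnames(f$U)) stop("unknown trait: ", trait)
  unknown <- setdiff(line_ids, rownames(f$U))
  if (length(unknown))
    stop("line(s) not in fit: ", paste(unknown, collapse = ", "))
  f$mu[trait] + f$U[line_ids, trait]
}
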