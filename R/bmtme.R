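#' Build the multi-trait multi-environment design
#'
#' Stacks the response environment-major: j = n * l rows, the block for
#' each environment holding the n lines in a fixed declared order. The
#' environment design X (j x l), genotype incidence Z1 (j x n) and
#' interaction incidence Z2 (j x n*l) are implicit in this canonical
#' ordering (each row carries exactly one 1 in each). Cells without an
#' adjusted mean are marked for data augmentation.
#'
#' @param b a [blue_table].
#' @param traits trait names (default: all present).
#' @param envs environment ids (default: all present).
#' @return list of class `mtme_spec`: `Y` (j x t response, `NA` = missing),
#'   `line_ids`, `env_ids`, `trait_names`, `row_line`, `row_env`.
#' @export
build_mtme_design <- function(b, traits = NULL, envs = NULL) {
  if (is.null(traits)) traits <- sort(unique(b$trait))
  if (is.null(envs)) envs <- sort(unique(b$env))
  d <- b[b$trait %in% traits & b$env %in% envs, , drop = FALSE]
  lines <- sort(unique(d$line))
  absent <- setdiff(unique(b$line), unique(d$line))
  if (length(lines) == 0) stop("no lines present in any selected environment")
  n <- length(lines); l <- length(envs); t <- length(traits)
  Y <- matrix(NA_real_, n * l, t,
              dimnames = list(NULL, traits))
  row_env <- rep(envs, each = n)
  row_line <- rep(lines, times = l)
  ridx <- (match(d$env, envs) - 1L) * n + match(d$line, lines)
  Y[cbind(ridx, match(d$trait, traits))] <- d$value
  rownames(Y) <- paste(row_env, row_line, sep = ":")
  structure(list(Y = Y, line_ids = lines, env_ids = envs,
                 trait_names = traits, row_line = row_line,
                 row_env = row_env),
            class = "mtme_spec")
}

#' Bayesian multi-trait multi-environment genomic model
#'
#' Fits Y = X Beta + Z1 b1 + Z2 b2 + E, where Beta (l x t) are fixed
#' environment-by-trait means, b1 (n x t) ~ MN(0, G, Sigma_t) are genotype
#' main effects with unstructured trait covariance, b2 (n*l x t) ~
#' MN(0, Sigma_E (x) G, Sigma_t) are genotype-by-environment-by-trait
#' effects with Kronecker covariance between environments and lines, and
#' the residual rows are iid N(0, Re) with unstructured Re. All covariance
#' full conditionals are inverse-Wishart; the sampler works in the
#' eigenbases of G and Sigma_E so the Kronecker covariance is never formed
#' as a dense j x j matrix. Missing cells are data-augmented, which is how
#' held-out lines and held-out environments (sparse testing) are predicted.
#'
#' Priors: Beta flat; Sigma_t ~ IW(t + 2, I); Sigma_E ~ IW(l + 2, I);
#' Re ~ IW(t + 2, I). The scale split between Sigma_E and Sigma_t is
#' identified because Sigma_t also governs the genotype main effects b1.
#'
#' @param spec an `mtme_spec` from [build_mtme_design()], or a matrix Y
#'   (then `row_line`/`row_env` style metadata must be attached via spec).
#' @param G relationship matrix over the spec's lines (PSD).
#' @param cfg a [gibbs_config].
#' @return list of class `mtme_fit` with posterior means `Beta` (l x t),
#'   `B1` (n x t), `B2` (j x t), `Sigma_t`, `Sigma_E`, `Re`, draw matrices
#'   and chain info.
#' @export
fit_mtme <- function(spec, G, cfg = gibbs_config()) {
  stopifnot(inherits(spec, "mtme_spec"))
  Y <- spec$Y
  n <- length(spec$line_ids); l <- length(spec$env_ids)
  t <- length(spec$trait_names)
  obs_per_col <- sapply(seq_len(t), function(a)
    tapply(!is.na(Y[, a]), spec$row_env, sum))
  if (any(obs_per_col < 5)) {
    bad <- which(obs_per_col < 5, arr.ind = TRUE)
    stop(sprintf("underdetermined (env, trait) column: (%s, %s) has < 5 observed cells",
                 spec$env_ids[bad[1, 1]], spec$trait_names[bad[1, 2]]))
  }
  if (!all(spec$line_ids %in% rownames(G))) stop("spec lines missing from G")
  Gs <- unclass(G)[spec$line_ids, spec$line_ids]
  e <- eigen(Gs, symmetric = TRUE)
  if (min(e$values) < -1e-6) stop("G not PSD; run make_psd() first")
  d <- pmax(e$values, 1e-8)
  miss <- matrix(as.integer(is.na(Y)), nrow(Y), t)
  Y0 <- Y; Y0[is.na(Y0)] <- 0
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- .mtme_gibbs(Y0, miss, e$vectors, d, l = l,
                     nu_t = t + 2, nu_E = l + 2, nu_R = t + 2,
                     n_burn = cfg$n_burn, n_iter = cfg$n_iter,
                     thin = cfg$thin)
  dn_t <- spec$trait_names
  out <- list(
    Beta = matrix(res$Beta_mean, l, t, dimnames = list(spec$env_ids, dn_t)),
    B1 = matrix(res$B1_mean, n, t, dimnames = list(spec$line_ids, dn_t)),
    B2 = matrix(res$B2_mean, n * l, t, dimnames = list(rownames(Y), dn_t)),
    Sigma_t = matrix(colMeans(res$St_draws), t, t, dimnames = list(dn_t, dn_t)),
    Sigma_E = matrix(colMeans(res$SE_draws), l, l,
                     dimnames = list(spec$env_ids, spec$env_ids)),
    Re = matrix(colMeans(res$Re_draws), t, t, dimnames = list(dn_t, dn_t)),
    B1_mcse = res$B1_sd / sqrt(res$n_kept),
    St_draws = res$St_draws, SE_draws = res$SE_draws, Re_draws = res$Re_draws,
    spec = spec, observed = !is.na(Y),
    chain = list(n_burn = cfg$n_burn, n_iter = cfg$n_iter, thin = cfg$thin,
                 n_kept = res$n_kept))
  class(out) <- "mtme_fit"
  out
}

#' @export
print.mtme_fit <- function(x, ...) {
  cat("mtme_fit:", nrow(x$B1), "lines x", ncol(x$B1), "traits x",
      nrow(x$Beta), "environments;", x$chain$n_kept, "retained draws\n")
  cat("environment correlations (posterior mean Sigma_E):\n")
  print(round(stats::cov2cor(x$Sigma_E), 3))
  invisible(x)
}

#' Cell predictions from an MTME fit
#'
#' prediction = Beta\[env, trait\] + B1\[line, trait\] + B2\[(env, line),
#' trait\]; defined for cells that were missing during fitting (their
#' effects were sampled by data augmentation).
#'
#' @param f an `mtme_fit`.
#' @param cells data.frame with columns line, env, trait.
#' @return `cells` with a `prediction` column appended.
#' @export
predict_mtme <- function(f, cells) {
  sp <- f$spec
  li <- match(cells$line, sp$line_ids)
  ei <- match(cells$env, sp$env_ids)
  ti <- match(cells$trait, sp$trait_names)
  if (anyNA(li) || anyNA(ei) || anyNA(ti)) {
    bad <- which(is.na(li) | is.na(ei) | is.na(ti))[1]
    stop(sprintf("unknown cell coordinate (line=%s, env=%s, trait=%s)",
                 cells$line[bad], cells$env[bad], cells$trait[bad]))
  }
  cells$prediction <- f$Beta[cbind(ei, ti)] + f$B1[cbind(li, ti)] +
    f$B2[cbind((ei - 1L) * length(sp$line_ids) + li, ti)]
  cells
}
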