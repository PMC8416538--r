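#' Single-trait GBLUP by spectral REML
#'
#' Fits y = 1*mu + u + e with u ~ N(0, G * sigma_g2) and e ~ N(0, I *
#' sigma_e2) for the phenotyped lines, maximizing the restricted likelihood
#' over the variance ratio delta = sigma_e2 / sigma_g2 by Brent search on
#' log(delta) after a single eigendecomposition of the training-line block
#' of G (the EMMA device). GEBVs are returned for every line in G:
#' unphenotyped lines are predicted through their genomic relationship to
#' the phenotyped ones (the conditional expectation under the joint
#' normal), which is equivalent to including them in the mixed-model
#' equations but cheaper.
#'
#' The model is the ridge-regression BLUP on centered markers: with
#' G = W W' / c, the matched marker-ridge penalty is kappa = c * delta and
#' the two give identical GEBVs.
#'
#' @param y named numeric vector of adjusted means (BLUEs), names = line
#'   ids; or a [blue_table] slice via `env`/`trait`.
#' @param G relationship matrix (`grm`) covering at least the phenotyped
#'   lines; all its lines receive GEBVs.
#' @param delta_bounds search interval for the variance ratio.
#' @param env,trait used to slice `y` when it is a `blue_table`.
#' @return list of class `st_fit`: `mu`, `gebv` (named, all lines of G),
#'   `sigma_g2`, `sigma_e2`, `delta`, `reml_loglik`, `train_ids`.
#' @export
fit_gblup <- function(y, G, delta_bounds = c(1e-5, 1e5),
                      env = NULL, trait = NULL) {
  if (inherits(y, "blue_table")) {
    d <- y[(is.null(env) | y$env == env) & (is.null(trait) | y$trait == trait), ]
    y <- stats::setNames(d$value, d$line)
  }
  y <- y[!is.na(y)]
  if (is.null(names(y))) stop("y must carry line ids as names")
  train <- intersect(rownames(G), names(y))
  if (length(train) < 10) stop("need >= 10 phenotyped lines present in G")
  yv <- y[train]
  ev_all <- eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_all) < -1e-6)
    stop("G is not positive semi-definite; run make_psd() first")
  if (stats::var(yv) == 0) {
    warning("zero phenotypic variance; returning null fit")
    gebv <- stats::setNames(rep(0, nrow(G)), rownames(G))
    return(structure(list(mu = unname(yv[1]), gebv = gebv, sigma_g2 = 0,
                          sigma_e2 = 0, delta = NA_real_,
                          reml_loglik = NA_real_, train_ids = train),
                     class = "st_fit"))
  }
  Gtr <- unclass(G)[train, train]
  e <- eigen(Gtr, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, yv))
  xt <- drop(crossprod(e$vectors, rep(1, length(yv))))
  n <- length(yv)
  # restricted log-likelihood profiled over mu and sigma_e2, as a function
  # of lambda = sigma_g2/sigma_e2 (so V = lambda*G + I in sigma_e2 units)
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    xvx <- sum(xt^2 * w); xvy <- sum(xt * yt * w); yvy <- sum(yt^2 * w)
    ypy <- yvy - xvy^2 / xvx
    0.5 * ((n - 1) * log(ypy / (n - 1)) + sum(log(lam * d + 1)) + log(xvx) +
           (n - 1))
  }
  lb <- log(1 / delta_bounds[2]); ub <- log(1 / delta_bounds[1])
  opt <- stats::optimize(negll, c(lb, ub), tol = 1e-10)
  lam <- exp(opt$minimum)
  w <- 1 / (lam * d + 1)
  xvx <- sum(xt^2 * w); xvy <- sum(xt * yt * w); yvy <- sum(yt^2 * w)
  mu <- xvy / xvx
  se2 <- (yvy - xvy^2 / xvx) / (n - 1)
  sg2 <- lam * se2
  # BLUP: u_hat = sigma_g2 * G[, train] %*% Vinv %*% (y - mu),
  # Vinv r computed in the eigenbasis of G[train, train]
  r <- yv - mu
  vinv_r <- e$vectors %*% ((crossprod(e$vectors, r) * w)) / se2
  gebv <- drop(sg2 * unclass(G)[, train, drop = FALSE] %*% vinv_r)
  names(gebv) <- rownames(G)
  structure(list(mu = mu, gebv = gebv, sigma_g2 = sg2, sigma_e2 = se2,
                 delta = 1 / lam, reml_loglik = -opt$objective,
                 train_ids = train),
            class = "st_fit")
}

#' @export
print.st_fit <- function(x, ...) {
  cat("st_fit: mu =", signif(x$mu, 4),
      " sigma_g2 =", signif(x$sigma_g2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4),
      " h2 =", signif(x$sigma_g2 / (x$sigma_g2 + x$sigma_e2), 3), "\n")
  invisible(x)
}

#' Predictions from a single-trait GBLUP fit
#'
#' Returns mu + GEBV for the requested lines (phenotyped or not, as long as
#' they were present in the relationship matrix at fitting time).
#'
#' @param f an `st_fit`.
#' @param line_ids lines to predict.
#' @return named numeric vector of predictions.
#' @export
predict_st <- function(f, line_ids) {
  unknown <- setdiff(line_ids, names(f$gebv))
  if (length(unknown))
    stop("line(s) not in the fitted relationship matrix: ",
         paste(unknown, collapse = ", "))
  f$mu + f$gebv[line_ids]
}

#' Explicit marker-ridge BLUP (reference path)
#'
#' Solves the ridge regression on centered markers at a given penalty:
#' beta_hat = (W'W + kappa I)^{-1} W' (y - mu), fitted values W beta_hat.
#' Used as an independent check of the GBLUP identity; not the production
#' path (it scales with marker count).
#'
#' @param y named numeric vector of phenotypes (training lines).
#' @param g a [marker_set] covering training and prediction lines.
#' @param kappa ridge penalty on marker effects.
#' @param mu intercept to center `y` at.
#' @return named vector of genetic values (W beta_hat) for all lines of `g`.
#' @export
ridge_blup_markers <- function(y, g, kappa, mu) {
  W <- center_dosages(g)
  tr <- match(names(y), g$line_ids)
  Wt <- W[tr, , drop = FALSE]
  beta <- solve(crossprod(Wt) + diag(kappa, ncol(Wt)), crossprod(Wt, y - mu))
  stats::setNames(drop(W %*% beta), g$line_ids)
}
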