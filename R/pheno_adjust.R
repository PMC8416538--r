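#' Per-environment adjusted means (BLUEs) and heritability components
#'
#' Fits, for one trait in one environment, the randomized-complete-block
#' model value = mean + replicate + genotype + error with genotype fixed and
#' replicate random, and returns the genotype BLUEs (mean + genotype effect).
#' A companion fit with genotype random supplies the REML variance
#' components used for broad-sense heritability on an entry-mean basis.
#'
#' @param p a [plot_table].
#' @param env environment id.
#' @param trait trait name.
#' @return A list of class `env_blues` with elements `blues` (data.frame
#'   line, env, trait, value), `varcomp` (a [var_comp]) and `mu`.
#' @export
fit_env_blues <- function(p, env, trait) {
  d <- p[p$env == env & p$trait == trait & !is.na(p$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait '", trait,
                         "' in environment '", env, "'")
  if (length(unique(d$line)) < 2) stop("need >= 2 lines with data in ", env)
  n_rep <- length(unique(d$rep))
  if (n_rep == 1L || length(unique(d$line)) == nrow(d)) {
    # single replicate: the BLUE is the observation itself
    blues <- stats::aggregate(value ~ line, d, mean)
    vc <- var_comp(NA_real_, NA_real_, n_rep = n_rep)
  } else {
    balanced <- all(table(d$line, d$rep) == 1L)
    fit <- if (balanced) NULL else try_lmer(value ~ 0 + line + (1 | rep), d)
    if (is.null(fit)) {
      # balanced complete blocks (or degenerate designs): the BLUE is the
      # block-adjusted line mean, exactly
      adj <- d$value - stats::ave(d$value, d$rep) + mean(d$value)
      blues <- stats::aggregate(list(value = adj), list(line = d$line), mean)
    } else {
      b <- lme4::fixef(fit)
      blues <- data.frame(line = sub("^line", "", names(b)), value = unname(b))
    }
    rfit <- try_lmer(value ~ (1 | line) + (1 | rep), d)
    if (is.null(rfit)) {
      adj <- d$value - stats::ave(d$value, d$rep) + mean(d$value)
      v2 <- reml_two_component(adj, d$line, n_rep = n_rep)
      vc <- var_comp(v2$sigma_g2, v2$sigma_e2, 0, n_rep)
    } else {
      vcs <- as.data.frame(lme4::VarCorr(rfit))
      getv <- function(g) { i <- match(g, vcs$grp); if (is.na(i)) 0 else vcs$vcov[i] }
      vc <- var_comp(sigma_g2 = getv("line"), sigma_e2 = getv("Residual"),
                     sigma_r2 = getv("rep"), n_rep = n_rep)
    }
  }
  missing_lines <- setdiff(unique(p$line[p$env == env]), blues$line)
  if (length(missing_lines))
    warning("lines without '", trait, "' observations in ", env, " omitted: ",
            paste(missing_lines, collapse = ", "))
  structure(list(
    blues = data.frame(line = blues$line, env = env, trait = trait,
                       value = blues$value, row.names = NULL),
    varcomp = vc, mu = mean(blues$value)),
    class = "env_blues")
}

# lme4 wrappers: quiet fits, NULL (or next formula) on failure so tiny or
# degenerate designs can fall back to simpler models
try_lmer <- function(formula, data) {
  tryCatch(suppressWarnings(suppressMessages(
    lme4::lmer(formula, data = data,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)))),
    error = function(e) NULL)
}

try_lmer_seq <- function(formulas, data) {
  for (f in formulas) {
    fit <- try_lmer(f, data)
    if (!is.null(fit)) return(fit)
  }
  stop("mixed-model fit failed for every candidate random-effect structure")
}

#' Across-environment adjusted means or predictions
#'
#' Fits value = mean + environment + replicate(environment) + genotype +
#' genotype x environment + error, with environment, replicate-within-
#' environment and the interaction random. The genotype enters fixed
#' (`mode = "blue"`, adjusted means) or random (`mode = "blup"`, shrunken
#' predictions).
#'
#' @param p a [plot_table].
#' @param trait trait name.
#' @param mode `"blue"` or `"blup"`.
#' @return list with `values` (data.frame line, trait, value), `varcomp`,
#'   `mu`.
#' @export
fit_across_env <- function(p, trait, mode = c("blue", "blup")) {
  mode <- match.arg(mode)
  d <- p[p$trait == trait & !is.na(p$value), , drop = FALSE]
  if (nrow(d) == 0) stop("trait '", trait, "' absent from all environments")
  if (length(unique(d$env)) < 2) stop("need >= 2 environments")
  d$line <- factor(d$line); d$env <- factor(d$env)
  d$rep_in_env <- interaction(d$env, d$rep, drop = TRUE)
  d$gxe <- interaction(d$line, d$env, drop = TRUE)
  fit <- NULL
  if (mode == "blue") {
    if (all(table(d$line, d$rep_in_env) == 1L)) {
      # balanced complete design: BLUE = block-adjusted line mean, exactly
      adj <- d$value - stats::ave(d$value, d$rep_in_env) + mean(d$value)
      vals <- stats::aggregate(list(value = adj), list(line = d$line), mean)
    } else {
      fit <- try_lmer_seq(
        list(value ~ 0 + line + (1 | env) + (1 | rep_in_env) + (1 | gxe),
             value ~ 0 + line + (1 | env) + (1 | rep_in_env),
             value ~ 0 + line + (1 | env)), d)
      b <- lme4::fixef(fit)
      vals <- data.frame(line = sub("^line", "", names(b)), value = unname(b))
    }
    mu <- mean(vals$value)
  } else {
    fit <- try_lmer_seq(
      list(value ~ (1 | line) + (1 | env) + (1 | rep_in_env) + (1 | gxe),
           value ~ (1 | line) + (1 | env) + (1 | rep_in_env),
           value ~ (1 | line) + (1 | env)), d)
    mu <- unname(lme4::fixef(fit)[1])
    re <- lme4::ranef(fit)$line
    vals <- data.frame(line = rownames(re), value = mu + re[[1]])
  }
  if (is.null(fit)) {
    vc <- var_comp(NA_real_, NA_real_, n_rep = length(unique(d$rep)))
  } else {
    vcs <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(g) { i <- match(g, vcs$grp); if (is.na(i)) 0 else vcs$vcov[i] }
    vc <- var_comp(sigma_g2 = if (mode == "blup") getv("line") else NA_real_,
                   sigma_e2 = getv("Residual"), sigma_r2 = getv("rep_in_env"),
                   n_rep = length(unique(d$rep)))
  }
  list(values = data.frame(line = vals$line, trait = trait,
                           value = vals$value, row.names = NULL),
       varcomp = vc, mu = mu)
}

#' Variance components of a replicated trial
#'
#' @param sigma_g2 genetic variance (>= 0).
#' @param sigma_e2 residual variance (>= 0).
#' @param sigma_r2 replicate (block) variance (>= 0).
#' @param n_rep replicate count used for entry-mean heritability.
#' @return list of class `var_comp`.
#' @export
var_comp <- function(sigma_g2, sigma_e2, sigma_r2 = 0, n_rep = 1L) {
  stopifnot(is.na(sigma_g2) || sigma_g2 >= 0,
            is.na(sigma_e2) || sigma_e2 >= 0)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 sigma_r2 = sigma_r2, n_rep = as.integer(n_rep)),
            class = "var_comp")
}

#' EM-REML for the one-way random-effects model
#'
#' Estimates (genetic, residual) variance components for observations
#' grouped by line, y = mean + line + error with line random, by EM-REML
#' iterated to relative tolerance `tol` with components floored at zero.
#' On balanced data this reproduces the ANOVA closed form
#' sigma_e2 = MSE, sigma_g2 = (MSB - MSE) / r.
#'
#' @param y numeric vector of observations.
#' @param group grouping factor (line), same length as `y`.
#' @param n_rep replicate count recorded in the result (defaults to the
#'   median group size).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return A [var_comp].
#' @export
reml_two_component <- function(y, group, n_rep = NULL, tol = 1e-8,
                               max_iter = 10000L) {
  keep <- !is.na(y)
  y <- y[keep]; group <- factor(group[keep])
  g <- nlevels(group); N <- length(y)
  if (g < 2) stop("need >= 2 groups")
  ni <- as.vector(table(group))
  if (all(ni == 1)) stop("no replication anywhere: residual variance unidentifiable")
  if (is.null(n_rep)) n_rep <- as.integer(round(stats::median(ni)))
  ybar <- tapply(y, group, mean)
  ssw <- sum((y - ybar[group])^2)
  # starting values from the method of moments
  se2 <- max(ssw / max(N - g, 1), stats::var(y) * 0.5, 1e-10)
  sa2 <- max(stats::var(as.vector(ybar)) - se2 / mean(ni), 1e-10)
  for (it in seq_len(max_iter)) {
    wi <- ni / (se2 + ni * sa2)              # per-group GLS weights on means
    mu <- sum(wi * ybar) / sum(wi)
    shrink <- ni * sa2 / (se2 + ni * sa2)
    a <- shrink * (ybar - mu)                # BLUPs of group effects
    # EM-REML trace terms: tr(Z'PZ) and tr(P) in per-group closed form
    # (rank-one correction accounts for the estimated grand mean)
    tZPZ <- sum(ni / (se2 + ni * sa2)) - sum(wi^2) / sum(wi)
    trP <- (N - g) / se2 + sum(1 / (se2 + ni * sa2)) - sum(wi^2 / ni) / sum(wi)
    e <- y - mu - a[group]
    sa2_new <- (sum(a^2) + sa2 * (g - sa2 * tZPZ)) / g
    se2_new <- (sum(e^2) + se2 * (N - se2 * trP)) / N
    sa2_new <- max(sa2_new, 0); se2_new <- max(se2_new, 1e-12)
    conv <- abs(sa2_new - sa2) <= tol * (abs(sa2) + tol) &&
            abs(se2_new - se2) <= tol * (abs(se2) + tol)
    sa2 <- sa2_new; se2 <- se2_new
    if (conv) break
  }
  if (sa2 < 1e-10) sa2 <- 0
  if (se2 <= 1e-10) se2 <- 0
  var_comp(sigma_g2 = sa2, sigma_e2 = se2, n_rep = n_rep)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma_g2 / (sigma_g2 + sigma_e2 / n_rep).
#'
#' @param v a [var_comp].
#' @return heritability in \[0, 1\], or `NA` with a warning when both
#'   components are zero.
#' @export
heritability <- function(v) {
  if (is.na(v$sigma_g2) || is.na(v$sigma_e2)) {
    warning("variance components unavailable; heritability undefined")
    return(NA_real_)
  }
  if (v$sigma_g2 == 0 && v$sigma_e2 == 0) {
    warning("both variance components zero; heritability undefined")
    return(NA_real_)
  }
  if (v$sigma_e2 == 0) return(1)
  v$sigma_g2 / (v$sigma_g2 + v$sigma_e2 / v$n_rep)
}

#' Adjusted-mean (BLUE) tables
#'
#' A `blue_table` is a long data.frame (line, env, trait, value) of adjusted
#' genotype means — the response of every prediction model in the package.
#' `env_blues_table()` assembles one by running [fit_env_blues()] over all
#' (environment, trait) combinations present.
#'
#' @param df data.frame with columns line, env, trait, value.
#' @return data.frame of class `blue_table`.
#' @export
blue_table <- function(df) {
  need <- c("line", "env", "trait", "value")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)[need]
  for (cn in c("line", "env", "trait")) df[[cn]] <- as.character(df[[cn]])
  key <- paste(df$line, df$env, df$trait, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (line, env, trait) entries")
  class(df) <- c("blue_table", "data.frame")
  df
}

#' @rdname blue_table
#' @param p a [plot_table].
#' @export
env_blues_table <- function(p) {
  combos <- unique(p[!is.na(p$value), c("env", "trait")])
  pieces <- vector("list", nrow(combos)); vcs <- list()
  for (i in seq_len(nrow(combos))) {
    f <- fit_env_blues(p, combos$env[i], combos$trait[i])
    pieces[[i]] <- f$blues
    vcs[[paste(combos$env[i], combos$trait[i], sep = ":")]] <- f$varcomp
  }
  out <- blue_table(do.call(rbind, pieces))
  attr(out, "varcomp") <- vcs
  out
}

#' Wide line x trait (or line x environment) matrix from a blue_table
#'
#' @param b a [blue_table].
#' @param env restrict to one environment (traits become columns); if NULL
#'   and one trait given, environments become columns.
#' @param trait restrict to one trait.
#' @keywords internal
blue_matrix <- function(b, env = NULL, trait = NULL) {
  d <- b
  if (!is.null(env)) d <- d[d$env %in% env, , drop = FALSE]
  if (!is.null(trait)) d <- d[d$trait %in% trait, , drop = FALSE]
  col <- if (!is.null(env) && length(env) == 1) "trait" else "env"
  lines <- unique(d$line); cols <- unique(d[[col]])
  m <- matrix(NA_real_, length(lines), length(cols),
              dimnames = list(lines, cols))
  m[cbind(match(d$line, lines), match(d[[col]], cols))] <- d$value
  m
}

#' Pairwise Pearson correlations among traits or environments
#'
#' Computed on line-level adjusted means with pairwise-complete
#' observations. `trait_correlations()` correlates traits within (or
#' averaged over) environments; `env_correlations()` correlates the
#' environment columns of a single trait.
#'
#' @param b a [blue_table].
#' @param traits traits to include (default: all present).
#' @param env optional single environment; default averages each line's
#'   values over environments first.
#' @return symmetric correlation matrix with unit diagonal, class
#'   `corr_matrix` with a `kind` attribute.
#' @export
trait_correlations <- function(b, traits = NULL, env = NULL) {
  if (is.null(traits)) traits <- unique(b$trait)
  d <- b[b$trait %in% traits, , drop = FALSE]
  if (!is.null(env)) d <- d[d$env %in% env, , drop = FALSE]
  agg <- stats::aggregate(value ~ line + trait, d, mean)
  lines <- unique(agg$line)
  m <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  m[cbind(match(agg$line, lines), match(agg$trait, traits))] <- agg$value
  corr_from_matrix(m, "pearson_phenotypic")
}

#' @rdname trait_correlations
#' @param trait single trait for environment correlations.
#' @export
env_correlations <- function(b, trait) {
  m <- blue_matrix(b, trait = trait)
  corr_from_matrix(m, "pearson_phenotypic")
}

corr_from_matrix <- function(m, kind) {
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "),
            "; their correlations are NA")
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  structure(cc, class = c("corr_matrix", "matrix"), kind = kind)
}

#' Genetic correlations from a multi-trait fit
#'
#' Converts the posterior-mean genetic covariance of a [fit_mt()] or
#' [fit_mtme()] result to a correlation matrix; a non-PSD posterior mean is
#' repaired via [make_psd()] with a warning.
#'
#' @param f an `mt_fit` or `mtme_fit`.
#' @return correlation matrix of class `corr_matrix`, kind `"genetic"`.
#' @export
genetic_correlations_from_fit <- function(f) {
  S <- f$Sigma_t
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    warning("posterior-mean genetic covariance not PSD; repairing")
    S <- make_psd(S)
  }
  cc <- stats::cov2cor(S)
  structure(cc, class = c("corr_matrix", "matrix"), kind = "genetic")
}
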