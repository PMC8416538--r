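#' Simulation configuration for synthetic breeding trials
#'
#' Describes a multi-family line panel evaluated for t traits in l
#' environments with r complete blocks — the structure of a winter-wheat
#' advanced/elite yield-trial season: ~150 lines from related families,
#' genotyped at genome-wide SNPs, five locations, two replicates, trait
#' heritabilities between 0.6 and 0.95 with a lower-heritability yield-like
#' trait, and a negative yield-protein genetic correlation.
#'
#' Genetic signal follows the MTME generative model: genotype main effects
#' B1 ~ MN(0, G, Sigma_t) plus genotype-by-environment effects
#' B2 ~ MN(0, gxe_ratio * Sigma_E (x) G, Sigma_t); plot values add an
#' environment-by-trait mean, a random complete-block effect and plot
#' noise. Residual variance is calibrated per (environment, trait) from the
#' realized genetic variance so the target entry-mean heritabilities are
#' hit tightly, not just in expectation.
#'
#' @param n_lines number of lines.
#' @param n_markers number of SNPs.
#' @param n_families number of families the lines descend from.
#' @param n_envs number of environments.
#' @param n_reps complete blocks per environment.
#' @param traits character vector of trait names.
#' @param h2 per-trait target entry-mean heritability (recycled over
#'   environments) or a n_envs x t matrix.
#' @param Sigma_t_corr t x t genetic correlation matrix among traits.
#' @param Sigma_E_corr l x l correlation matrix among environments for the
#'   GxE effects.
#' @param gxe_ratio variance of GxE effects relative to genotype main
#'   effects (1 = equal shares).
#' @param main_var variance scale of the genotype main effect (0 removes
#'   it, leaving purely environment-specific genetic signal).
#' @param env_means l x t matrix of environment-by-trait means.
#' @param block_sd_frac block-effect sd as a fraction of the genetic sd.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 150, n_markers = 2000, n_families = 15,
                       n_envs = 5, n_reps = 2,
                       traits = c("YLD", "PROT"),
                       h2 = c(0.6, 0.8),
                       Sigma_t_corr = NULL, Sigma_E_corr = NULL,
                       gxe_ratio = 1, main_var = 1, env_means = NULL,
                       block_sd_frac = 0.5, seed = 1L) {
  traits <- as.character(unlist(traits))
  if (is.list(h2)) h2 <- unlist(h2)
  t <- length(traits)
  if (is.null(Sigma_t_corr)) {
    Sigma_t_corr <- diag(t)
    if (t == 2) Sigma_t_corr[1, 2] <- Sigma_t_corr[2, 1] <- -0.54
  }
  if (is.null(Sigma_E_corr)) {
    Sigma_E_corr <- matrix(0.5, n_envs, n_envs); diag(Sigma_E_corr) <- 1
  }
  check_corr <- function(m, what) {
    if (!isSymmetric(m) || any(abs(diag(m) - 1) > 1e-12))
      stop(what, " must be a correlation matrix (symmetric, unit diagonal)")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(what, " is not positive semi-definite")
  }
  check_corr(Sigma_t_corr, "Sigma_t_corr"); check_corr(Sigma_E_corr, "Sigma_E_corr")
  if (is.null(dim(h2))) h2 <- matrix(h2, n_envs, t, byrow = TRUE)
  stopifnot(all(h2 > 0 & h2 < 1), nrow(h2) == n_envs, ncol(h2) == t)
  if (is.null(env_means))
    env_means <- outer(seq_len(n_envs) - (n_envs + 1) / 2,
                       rep(1, t)) * 0.5
  if (n_families > n_lines) stop("n_families > n_lines")
  structure(list(n_lines = n_lines, n_markers = n_markers,
                 n_families = n_families, n_envs = n_envs, n_reps = n_reps,
                 traits = traits, h2 = h2, Sigma_t_corr = Sigma_t_corr,
                 Sigma_E_corr = Sigma_E_corr, gxe_ratio = gxe_ratio,
                 main_var = main_var,
                 env_means = env_means, block_sd_frac = block_sd_frac,
                 seed = as.integer(seed), rng = "Mersenne-Twister"),
            class = "sim_config")
}

#' Simulate a family-structured SNP panel
#'
#' Marker allele frequencies are drawn from U(0.05, 0.5). Each family gets
#' four founder gametes (haplotypes) drawn at those frequencies; each line
#' inherits, independently per genome block (20 blocks), two of its
#' family's gametes. Lines within a family therefore share long founder
#' segments, giving the elevated within-family relatedness of a breeding
#' panel without simulating meiosis.
#'
#' @param cfg a [sim_config].
#' @return a [marker_set] with lines `L001...` and a `family` attribute.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_lines; m <- cfg$n_markers
  if (m < 10) stop("need n_markers >= 10")
  p <- stats::runif(m, 0.05, 0.5)
  fam <- sort(rep_len(seq_len(cfg$n_families), n))
  n_blocks <- 20L
  block <- cut(seq_len(m), n_blocks, labels = FALSE)
  # founder gametes per family and per-line gamete picks per block
  gam <- vector("list", cfg$n_families)
  picks <- vector("list", n)
  for (f in seq_len(cfg$n_families)) {
    gam[[f]] <- matrix(stats::rbinom(4L * m, 1L, rep(p, each = 4L)),
                       nrow = 4L)
    for (i in which(fam == f))
      picks[[i]] <- matrix(sample.int(4L, 2L * n_blocks, replace = TRUE), 2L)
  }
  build <- function(cols) {
    dd <- matrix(0L, n, length(cols))
    for (i in seq_len(n)) {
      gm <- gam[[fam[i]]]
      pk <- picks[[i]]
      dd[i, ] <- gm[cbind(pk[1L, block[cols]], cols)] +
        gm[cbind(pk[2L, block[cols]], cols)]
    }
    dd
  }
  dos <- build(seq_len(m))
  # markers drifting to (near) fixation in the realized panel get fresh
  # founder alleles at intermediate frequency, keeping the panel segregating
  for (pass in 1:5) {
    pp <- colMeans(dos) / 2
    bad <- which(pmin(pp, 1 - pp) < 0.01)
    if (!length(bad)) break
    p[bad] <- stats::runif(length(bad), 0.25, 0.5)
    for (f in seq_len(cfg$n_families))
      gam[[f]][, bad] <- stats::rbinom(4L * length(bad), 1L,
                                       rep(p[bad], each = 4L))
    dos[, bad] <- build(bad)
  }
  rownames(dos) <- sprintf("L%03d", seq_len(n))
  colnames(dos) <- sprintf("M%05d", seq_len(m))
  out <- marker_set(dos,
                    chrom = paste0("chr", ((seq_len(m) - 1) %% 21) + 1),
                    pos = ((seq_len(m) - 1) %/% 21 + 1) * 1000L)
  attr(out, "family") <- stats::setNames(fam, rownames(dos))
  out
}

# draw X ~ MN(0, A, B) given eigen/chol factors: X = La %*% Z %*% t(Lb)
rmatnorm <- function(La, Lb) {
  Z <- matrix(stats::rnorm(ncol(La) * nrow(Lb)), ncol(La), nrow(Lb))
  La %*% Z %*% t(Lb)
}

chol_psd <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, eps)), nrow(m))
}

#' Simulate plot-level multi-trait multi-environment phenotypes
#'
#' Draws genotype main effects B1 ~ MN(0, G, Sigma_t) and GxE effects
#' B2 ~ MN(0, gxe_ratio * Sigma_E (x) G, Sigma_t) (G from [grm_vanraden()]
#' on the supplied genotypes), then builds plot values
#' env_mean + B1 + B2 + block + noise for every replicate. The residual sd
#' for each (environment, trait) is set from the realized genetic variance
#' in that environment so the target heritability is met exactly on the
#' entry-mean basis.
#'
#' @param g a [marker_set] (typically from [simulate_genotypes()]).
#' @param cfg the [sim_config].
#' @param G optional relationship matrix to draw genetic effects from
#'   (defaults to the VanRaden GRM of `g`); lets constructed covariance
#'   structures — e.g. a block-diagonal G for a no-information control —
#'   drive the simulation.
#' @return list of class `sim_data`: `plots` (a [plot_table]), `truth`
#'   (class `sim_truth`: B1, B2, Sigma_t, Sigma_E, residual variances,
#'   realized h2, genetic values per env), `geno`, `config`.
#' @export
simulate_phenotypes <- function(g, cfg, G = NULL) {
  set.seed(cfg$seed + 1L)
  if (is.null(G)) G <- make_psd(grm_vanraden(impute_mean(g)))
  n <- nrow(G); l <- cfg$n_envs; t <- length(cfg$traits)
  LG <- chol_psd(unclass(G))
  Lt <- chol_psd(cfg$Sigma_t_corr)
  LE <- chol_psd(cfg$Sigma_E_corr * cfg$gxe_ratio)
  B1 <- sqrt(cfg$main_var %||% 1) * rmatnorm(LG, Lt)
  dimnames(B1) <- list(rownames(G), cfg$traits)
  # B2 ~ MN(0, Sigma_E (x) G, Sigma_t): row factor applied as LG then LE
  # per trait slice, trait factor Lt on the right of the stacked matrix
  Zc <- array(stats::rnorm(n * l * t), c(n, l, t))
  Xmat <- matrix(0, n * l, t)
  for (a in seq_len(t)) {
    Xa <- LG %*% Zc[, , a] %*% t(LE)
    for (e in seq_len(l)) Xmat[(e - 1) * n + seq_len(n), a] <- Xa[, e]
  }
  B2m0 <- Xmat %*% t(Lt)                       # env-major (n*l) x t
  B2 <- array(0, c(n, l, t))
  for (e in seq_len(l)) B2[, e, ] <- B2m0[(e - 1) * n + seq_len(n), ]
  env_ids <- sprintf("E%d", seq_len(l))
  rep_ids <- sprintf("R%d", seq_len(cfg$n_reps))
  recs <- vector("list", l * t)
  resid_var <- matrix(NA_real_, l, t, dimnames = list(env_ids, cfg$traits))
  real_h2 <- resid_var
  k <- 0
  for (e in seq_len(l)) for (a in seq_len(t)) {
    gv <- B1[, a] + B2[, e, a]                 # total genetic value, env e
    vg <- stats::var(gv)
    h2t <- cfg$h2[e, a]
    se2 <- vg * cfg$n_reps * (1 - h2t) / h2t   # entry-mean calibration
    resid_var[e, a] <- se2
    real_h2[e, a] <- vg / (vg + se2 / cfg$n_reps)
    sb <- cfg$block_sd_frac * sqrt(vg)
    blk <- stats::rnorm(cfg$n_reps, 0, sb)
    for (r in seq_len(cfg$n_reps)) {
      k <- k + 1
      recs[[k]] <- data.frame(
        line = rownames(G), env = env_ids[e], rep = rep_ids[r],
        trait = cfg$traits[a],
        value = cfg$env_means[e, a] + gv + blk[r] +
          stats::rnorm(n, 0, sqrt(se2)))
    }
  }
  plots <- plot_table(do.call(rbind, recs))
  B2m <- B2m0
  rownames(B2m) <- paste(rep(env_ids, each = n), rep(rownames(G), l),
                         sep = ":")
  colnames(B2m) <- cfg$traits
  truth <- structure(list(
    B1 = B1, B2 = B2m,
    Sigma_t = cfg$Sigma_t_corr,
    Sigma_E = cfg$Sigma_E_corr * cfg$gxe_ratio,
    resid_var = resid_var, realized_h2 = real_h2,
    genetic_value = lapply(stats::setNames(seq_len(l), env_ids),
                           function(e) B1 + B2[, e, ]),
    seed = cfg$seed), class = "sim_truth")
  structure(list(plots = plots, truth = truth, geno = g, config = cfg,
                 G = G), class = "sim_data")
}

#' Season-contrast scenario presets
#'
#' Two named configurations emulating the contrast between a season with
#' weak trait/environment correlations and one with strong correlations:
#' `season_low` (trait correlation 0.3, environment correlations 0.3) and
#' `season_high` (trait correlation 0.9, environment correlations 0.7).
#' Both carry a low-heritability primary trait (`YLD`, h2 = 0.3) and a
#' high-heritability secondary trait (`SEC`, h2 = 0.7) so that the value of
#' borrowing information across traits and environments differs sharply
#' between the two presets.
#'
#' @param n_lines,n_markers panel size (defaults sized for repeated CV).
#' @param seed base seed.
#' @return named list of two [sim_config]s.
#' @export
make_paper_like_scenarios <- function(n_lines = 150, n_markers = 1000,
                                      seed = 1L) {
  mk <- function(rt, re) {
    St <- matrix(c(1, rt, rt, 1), 2)
    SE <- matrix(re, 5, 5); diag(SE) <- 1
    sim_config(n_lines = n_lines, n_markers = n_markers,
               traits = c("YLD", "SEC"), h2 = c(0.3, 0.7),
               Sigma_t_corr = St, Sigma_E_corr = SE, seed = seed)
  }
  list(season_low = mk(0.3, 0.3), season_high = mk(0.9, 0.7))
}

#' Serialize a simulated dataset to the package's text dialects
#'
#' Writes genotype TSV (+ map), phenotype TSV, and the truth as JSON plus
#' matrix TSVs, so a simulated study round-trips through [read_genotypes()]
#' and [read_phenotypes()].
#'
#' @param sim a `sim_data` from [simulate_phenotypes()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(geno = file.path(dir, "genotypes.tsv"),
         map = file.path(dir, "marker_map.tsv"),
         pheno = file.path(dir, "phenotypes.tsv"),
         truth = file.path(dir, "truth.json"),
         b1 = file.path(dir, "truth_B1.tsv"),
         b2 = file.path(dir, "truth_B2.tsv"))
  write_genotypes(sim$geno, f["geno"], f["map"])
  write_phenotypes(sim$plots, f["pheno"])
  tr <- sim$truth
  jsonlite::write_json(list(
    Sigma_t = tr$Sigma_t, Sigma_E = tr$Sigma_E,
    resid_var = tr$resid_var, realized_h2 = tr$realized_h2,
    seed = tr$seed, rng = sim$config$rng), f["truth"], digits = NA)
  utils::write.table(data.frame(line = rownames(tr$B1), tr$B1),
                     f["b1"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = rownames(tr$B2), tr$B2),
                     f["b2"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(f)
}
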