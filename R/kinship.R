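#' Genomic relationship matrices
#'
#' `grm_vanraden()` builds the additive genomic relationship matrix
#' G = W W' / (2 * sum_k p_k (1 - p_k)), where W is the dosage matrix with
#' each column centered at twice its allele frequency (p estimated from the
#' analyzed lines themselves). `kinship_centered_ibs()` builds the
#' centered-IBS kinship K = W W' / c with c = trace(W W') / n, so the mean
#' diagonal equals 1. Both require complete dosages — run [impute_mean()]
#' first.
#'
#' @param g a [marker_set] without missing dosages.
#' @return An n x n symmetric matrix of class `grm` with line ids as
#'   dimnames and a `method` attribute (`"vanraden"` or `"centered_ibs"`).
#' @export
grm_vanraden <- function(g) {
  W <- center_dosages(g)
  p <- attr(W, "p")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("no polymorphic markers: VanRaden denominator is zero")
  new_grm(tcrossprod(W) / denom, g$line_ids, "vanraden")
}

#' @rdname grm_vanraden
#' @export
kinship_centered_ibs <- function(g) {
  if (nrow(g$dosages) == 1L) # degenerate: a single line is its own reference
    return(new_grm(matrix(1, 1, 1), g$line_ids, "centered_ibs"))
  W <- center_dosages(g)
  WWt <- tcrossprod(W)
  c0 <- sum(diag(WWt)) / nrow(WWt)
  if (c0 <= 0) stop("no polymorphic markers: centered-IBS scale is zero")
  new_grm(WWt / c0, g$line_ids, "centered_ibs")
}

center_dosages <- function(g) {
  dos <- g$dosages
  if (anyNA(dos))
    stop("missing dosages present; run impute_mean() first")
  p <- colMeans(dos) / 2
  W <- sweep(dos, 2, 2 * p)
  attr(W, "p") <- p
  W
}

new_grm <- function(values, ids, method) {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("grm", "matrix"), method = method)
}

#' @export
print.grm <- function(x, ...) {
  cat("grm (", attr(x, "method"), "): ", nrow(x), " lines, mean diagonal ",
      signif(mean(diag(x)), 4), "\n", sep = "")
  invisible(x)
}

#' Repair a relationship matrix to positive semi-definiteness
#'
#' Eigenvalues below `eps` are clipped to `eps` and the matrix reconstructed;
#' eigenvectors are preserved, which matters for the spectral REML solver
#' downstream. A matrix already PSD (to within tolerance) is returned
#' unchanged.
#'
#' @param m symmetric numeric matrix (e.g. a `grm`).
#' @param eps clipping floor for eigenvalues.
#' @return The repaired matrix, same class/attributes as the input.
#' @export
make_psd <- function(m, eps = 1e-8) {
  if (!isSymmetric(unclass(m), tol = 1e-8))
    stop("make_psd() requires a symmetric matrix")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  attributes(out)$class <- class(m)
  attr(out, "method") <- attr(m, "method")
  out
}

#' Write / read a relationship matrix as TSV
#'
#' The TSV carries line ids as both header row and first column; the method
#' tag is logged to a JSON sidecar when `json_path` is given.
#'
#' @param m a `grm`.
#' @param path output TSV path.
#' @param json_path optional JSON sidecar path.
#' @export
write_grm <- function(m, path, json_path = NULL) {
  tab <- data.frame(line = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(method = attr(m, "method"), n = nrow(m)),
                         json_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  new_grm(as.matrix(tab), rownames(tab), "loaded")
}
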