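#' Marker dosage sets
#'
#' A `marker_set` holds a line x marker dosage matrix (0/1/2 counts of the
#' alternate or declared non-reference allele, `NA` for missing calls)
#' together with a marker map (chromosome, 1-based bp position). It is the
#' genomic input to the relationship-matrix builders and to the genomic
#' prediction models.
#'
#' @param dosages numeric matrix, lines in rows, markers in columns; entries
#'   in \{0, 1, 2\} or `NA`.
#' @param chrom character vector of chromosome labels, one per marker;
#'   `"unknown"` (or `"UN"`) marks unmapped markers.
#' @param pos integer vector of 1-based bp positions, one per marker.
#' @return An object of class `marker_set` with elements `dosages`, `chrom`,
#'   `pos`, `line_ids`, `marker_ids`.
#' @export
marker_set <- function(dosages, chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("L", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate marker ids")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate line ids")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("non-{0,1,2} dosage entries present")
  if (is.null(chrom)) chrom <- rep("unknown", ncol(dosages))
  if (is.null(pos)) pos <- rep(NA_integer_, ncol(dosages))
  stopifnot(length(chrom) == ncol(dosages), length(pos) == ncol(dosages))
  structure(
    list(dosages = dosages, chrom = as.character(chrom), pos = as.integer(pos),
         line_ids = rownames(dosages), marker_ids = colnames(dosages)),
    class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", length(x$line_ids), "lines x", length(x$marker_ids),
      "markers;", sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.marker_set <- function(x) dim(x$dosages)

#' Read genotypes from VCF or dosage TSV
#'
#' VCF records must be biallelic SNPs with GT calls; dosage is the count of
#' the ALT allele, `./.` maps to missing. The TSV dialect has a header row of
#' marker ids and a first column of line ids, entries in \{0,1,2\} with `NA`
#' or `.` for missing; an optional sidecar map TSV (columns marker, chrom,
#' pos) supplies the marker map, otherwise chromosomes are `"unknown"`.
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @param map_path optional sidecar map TSV for `format = "tsv"`.
#' @return A [marker_set].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path, map_path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multi-allelic VCF record(s): ",
         paste(fix[multi, "ID"], collapse = ", "),
         " at ", paste(fix[multi, "CHROM"], fix[multi, "POS"],
                       sep = ":", collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; any '.' in the call -> missing
  count_alt <- function(g) {
    ifelse(is.na(g) | grepl("\\.", g),
           NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                       dimnames = list(NULL, colnames(gt)))
  dos <- t(dos)                       # lines x markers
  mid <- fix[, "ID"]
  mid[is.na(mid) | mid == "."] <- paste(fix[, "CHROM"], fix[, "POS"],
                                        sep = "_")[is.na(mid) | mid == "."]
  colnames(dos) <- mid
  marker_set(dos, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

read_genotypes_tsv <- function(path, map_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                           na.strings = c("NA", "."))
  dos <- as.matrix(tab)
  storage.mode(dos) <- "double"
  bad <- which(!is.na(dos) & !(dos %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-{0,1,2} entry at line '%s', marker '%s'",
                 rownames(dos)[bad[1, 1]], colnames(dos)[bad[1, 2]]))
  chrom <- NULL; pos <- NULL
  if (!is.null(map_path)) {
    mp <- utils::read.delim(map_path, check.names = FALSE)
    idx <- match(colnames(dos), mp$marker)
    chrom <- ifelse(is.na(idx), "unknown", as.character(mp$chrom[idx]))
    pos <- ifelse(is.na(idx), NA_integer_, as.integer(mp$pos[idx]))
  }
  marker_set(dos, chrom = chrom, pos = pos)
}

#' Write a marker set as dosage TSV (+ map TSV)
#'
#' @param g a [marker_set].
#' @param path output TSV path.
#' @param map_path optional path for the sidecar marker map.
#' @export
write_genotypes <- function(g, path, map_path = NULL) {
  tab <- data.frame(line = g$line_ids, g$dosages, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(
      data.frame(marker = g$marker_ids, chrom = g$chrom, pos = g$pos),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-marker allele frequency and missingness
#'
#' @param g a [marker_set].
#' @return data.frame with columns marker, maf, missing_frac. MAF is
#'   min(p, 1 - p) with p = mean non-missing dosage / 2.
#' @export
marker_stats <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  data.frame(marker = g$marker_ids,
             maf = pmin(p, 1 - p),
             missing_frac = colMeans(is.na(g$dosages)),
             row.names = NULL)
}

#' Marker quality-control filter
#'
#' Removes, in order: markers with missing fraction above `max_missing`
#' (default 20%), markers with minor allele frequency below `min_maf`
#' (default 0.05, computed on non-missing calls), and, when `drop_unmapped`,
#' markers whose chromosome is `"unknown"`/`"UN"`.
#'
#' @param g a [marker_set].
#' @param max_missing maximum tolerated missing fraction.
#' @param min_maf minimum minor allele frequency.
#' @param drop_unmapped drop markers without a chromosome assignment?
#' @return The filtered [marker_set], with a `filter_report` attribute
#'   (list of counts removed per rule and retained total).
#' @export
filter_markers <- function(g, max_missing = 0.20, min_maf = 0.05,
                           drop_unmapped = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  miss <- colMeans(is.na(g$dosages))
  drop_miss <- miss > max_missing
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- !drop_miss & (is.nan(maf) | maf < min_maf)
  drop_map <- rep(FALSE, length(maf))
  if (drop_unmapped)
    drop_map <- !drop_miss & !drop_maf &
      (is.na(g$chrom) | g$chrom %in% c("unknown", "UN"))
  keep <- !(drop_miss | drop_maf | drop_map)
  if (!any(keep))
    stop("all markers removed by QC; review max_missing/min_maf thresholds")
  out <- marker_set(g$dosages[, keep, drop = FALSE],
                    chrom = g$chrom[keep], pos = g$pos[keep])
  attr(out, "filter_report") <- list(
    n_input = length(keep),
    removed_missing = sum(drop_miss),
    removed_maf = sum(drop_maf),
    removed_unmapped = sum(drop_map),
    n_retained = sum(keep),
    max_missing = max_missing, min_maf = min_maf)
  out
}

#' Marker-mean imputation of missing dosages
#'
#' Replaces each missing call by the marker's mean non-missing dosage
#' (real-valued dosages are allowed downstream). A haplotype-aware imputer is
#' deliberately out of scope; mean imputation preserves allele frequencies,
#' which is all the relationship-matrix builders consume.
#'
#' @param g a [marker_set].
#' @return A [marker_set] without missing entries.
#' @export
impute_mean <- function(g) {
  dos <- g$dosages
  nmiss <- colSums(is.na(dos))
  if (any(nmiss == nrow(dos)))
    stop("fully missing marker(s): ",
         paste(g$marker_ids[nmiss == nrow(dos)], collapse = ", "))
  if (any(nmiss > 0)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  out <- g
  out$dosages <- dos
  out
}

#' Plot-level phenotype tables
#'
#' A `plot_table` is a long-format data.frame of plot observations with
#' columns `line`, `env`, `rep`, `trait`, `value` — one row per plot per
#' trait. Replicates are complete blocks within an environment.
#'
#' @param df data.frame with columns line, env, rep, trait, value.
#' @return A data.frame of class `plot_table`.
#' @export
plot_table <- function(df) {
  need <- c("line", "env", "rep", "trait", "value")
  if (!all(need %in% names(df)))
    stop("plot table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (cn in c("line", "env", "rep", "trait")) df[[cn]] <- as.character(df[[cn]])
  df$value <- as.numeric(df$value)
  key <- paste(df$line, df$env, df$rep, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate plot record for (line=%s, env=%s, rep=%s, trait=%s)",
                 d$line, d$env, d$rep, d$trait))
  }
  class(df) <- c("plot_table", "data.frame")
  df
}

#' Read a long-format phenotype TSV
#'
#' Expects tab-delimited columns line, env, rep, trait, value; `"NA"` values
#' are retained as missing records.
#'
#' @param path TSV path.
#' @return A [plot_table].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = "NA", colClasses = "character")
  df$value <- suppressWarnings(as.numeric(df$value))
  plot_table(df)
}

#' Write a plot table as TSV
#' @param p a [plot_table].
#' @param path output path.
#' @export
write_phenotypes <- function(p, path) {
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
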