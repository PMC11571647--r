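#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' a positive geometric mean across samples, of the ratio of the sample's
#' count to the gene's geometric mean. The factor vector is rescaled to
#' geometric mean 1, so relative library depth is all that remains.
#'
#' @param counts Gene x sample count matrix (non-negative).
#' @return Named positive numeric vector of per-sample factors with
#'   geometric mean 1.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  log_gm <- rowMeans(log(counts))        # -Inf for genes with any zero
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has positive counts in every sample; filter genes first")
  ratios <- counts[use, , drop = FALSE] / exp(log_gm[use])
  sf <- apply(ratios, 2L, median)        # plain median of natural-scale ratios
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' Divides each sample column by its size factor. The result carries a
#' `normalized = TRUE` attribute.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Per-sample positive factors from [size_factors()].
#' @return Normalized gene x sample matrix.
#' @export
normalize_counts <- function(counts, factors) {
  stopifnot(is.matrix(counts), length(factors) == ncol(counts))
  if (any(factors <= 0)) stop("size factors must be positive")
  out <- sweep(counts, 2L, factors, "/")
  attr(out, "normalized") <- TRUE
  out
}

#' Standardize matrix rows to mean zero, unit sample variance
#'
#' Each row is centred and scaled with the n-1 variance convention.
#' Constant rows cannot be standardized; they are dropped with a warning
#' naming them, never silently zeroed.
#'
#' @param mat Numeric matrix (e.g. genes x samples).
#' @return Matrix with the same columns; constant rows removed.
#' @export
standardize_rows <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  s <- apply(mat, 1L, sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning("dropping ", sum(const), " constant row(s): ",
            paste(head(rownames(mat)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    mat <- mat[!const, , drop = FALSE]
    s <- s[!const]
  }
  (mat - rowMeans(mat)) / s
}

#' Standardize a vector to mean zero, unit sample variance
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardized vector (n-1 variance convention).
#' @export
standardize_vector <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Quality-control filter for genotypes
#'
#' Applies, in this fixed order: (1) remove individuals with call rate below
#' `ind_call_min`; (2) remove SNPs with call rate below `snp_call_min`;
#' (3) remove SNPs with minor allele frequency below `maf_min`. MAF is the
#' folded frequency of the less common allele, computed on non-missing
#' calls. The order matters and is PLINK-like: individual missingness is
#' resolved before per-SNP statistics.
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param snp_call_min Minimum per-SNP call rate (default 0.90).
#' @param ind_call_min Minimum per-individual call rate (default 0.90).
#' @return Filtered [genotype_matrix()]; errors if nothing survives.
#' @export
qc_filter_genotypes <- function(geno, maf_min = 0.05, snp_call_min = 0.90,
                                ind_call_min = 0.90) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  keep_ind <- rowMeans(!is.na(d)) >= ind_call_min
  d <- d[keep_ind, , drop = FALSE]
  if (nrow(d) == 0L) stop("no individuals pass the call-rate filter")
  keep_call <- colMeans(!is.na(d)) >= snp_call_min
  d <- d[, keep_call, drop = FALSE]
  maf <- snp_maf(d)
  keep_maf <- !is.na(maf) & maf >= maf_min
  d <- d[, keep_maf, drop = FALSE]
  if (ncol(d) == 0L) stop("no SNPs pass the QC filters")
  info <- geno$snp_info[match(colnames(d), geno$snp_info$snp_id), , drop = FALSE]
  rownames(info) <- NULL
  genotype_matrix(d, info)
}

#' Folded minor allele frequency per SNP
#'
#' @param dosage Sample x SNP dosage matrix (ALT-allele counts, NA missing).
#' @return Per-SNP MAF in `[0, 0.5]`, `NA` for all-missing SNPs.
#' @export
snp_maf <- function(dosage) {
  p_alt <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p_alt, 1 - p_alt)
}

#' Remove outlier samples from an expression matrix
#'
#' Flags samples whose Euclidean distance to the mean sample profile
#' exceeds mean + `n_sd` standard deviations of that distance statistic (a
#' connectivity-style summary that generalizes the fixed dendrogram-height
#' cut used on any one dataset). The threshold is recomputed from the data
#' at every call, so a second application on the cleaned matrix is not
#' guaranteed to remove nothing.
#'
#' @param expr Normalized gene x sample matrix.
#' @param n_sd Number of SDs beyond the mean distance (default 3).
#' @return List with `expr` (cleaned matrix) and `removed` (sample ids).
#' @export
remove_outlier_samples <- function(expr, n_sd = 3) {
  stopifnot(is.matrix(expr))
  centre <- rowMeans(expr)
  d <- sqrt(colSums((expr - centre)^2))
  thr <- mean(d) + n_sd * sd(d)
  removed <- colnames(expr)[d > thr]
  out <- expr[, d <= thr, drop = FALSE]
  if (ncol(out) < 10L) stop("fewer than 10 samples remain after outlier removal")
  if (length(removed))
    message("removed ", length(removed), " outlier sample(s): ",
            paste(removed, collapse = ", "))
  list(expr = out, removed = removed)
}

#' log2(x + 1) transform of a normalized count matrix
#'
#' Convenience step between normalization and the correlation- or
#' regression-based stages.
#'
#' @param norm_expr Normalized gene x sample matrix.
#' @return log2(x + 1) matrix.
#' @export
log_transform <- function(norm_expr) log2(norm_expr + 1)
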