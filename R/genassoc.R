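#' Genomic relationship matrix (centered-scaled)
#'
#' \eqn{K = WW'/p} with `W` the column-centred dosage matrix scaled per SNP
#' by \eqn{\sqrt{2 \cdot MAF (1 - MAF)}}. Missing dosages are mean-imputed
#' per SNP first (counts logged via message). Negative eigenvalues, if any,
#' are clipped to zero.
#'
#' @param geno A [genotype_matrix()] (ideally QC-filtered).
#' @return Symmetric PSD sample x sample matrix with average diagonal near 1.
#' @export
build_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  p <- ncol(d)
  if (p == 0L) stop("no SNPs to build a GRM from")
  n_miss <- sum(is.na(d))
  if (n_miss > 0L) {
    message("mean-imputing ", n_miss, " missing dosage call(s)")
    for (j in seq_len(p)) {
      mj <- is.na(d[, j])
      if (any(mj)) d[mj, j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  pf <- colMeans(d) / 2
  sc <- sqrt(2 * pf * (1 - pf))
  use <- sc > 0
  W <- sweep(d[, use, drop = FALSE], 2L, 2 * pf[use], "-")
  W <- sweep(W, 2L, sc[use], "/")
  K <- tcrossprod(W) / sum(use)
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 0) {
    message("clipping ", sum(ev$values < 0), " negative GRM eigenvalue(s)")
    K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- list(rownames(d), rownames(d))
  }
  K
}

#' Mixed-linear-model association scan (eGWAS)
#'
#' Per-SNP association of an expression (or trait) vector under
#' \eqn{y = \alpha + X\beta + u + \epsilon}, \eqn{u \sim N(0, \sigma^2_g K)}.
#' `K` is eigendecomposed once; the variance ratio is REML-estimated under
#' the null model and reused for every SNP (EMMAX-style approximation), and
#' each SNP gets a GLS effect, SE and Wald p-value. Missing dosages are
#' mean-imputed per SNP. Bonferroni thresholds and the genomic inflation
#' factor are attached.
#'
#' @param y Length-n phenotype/expression vector, aligned to the genotype
#'   samples.
#' @param geno A [genotype_matrix()].
#' @param K GRM from [build_grm()] (or any symmetric PSD matrix).
#' @param snps Optional character vector restricting the scan.
#' @param alpha Significance level for the Bonferroni threshold.
#' @return List of class `"assoc_result"`: `table` (snp_id, chrom, pos, maf,
#'   beta, se, p), `model = "LMM"`, `h2`, `lambda_gc`, `thresholds`, `n_used`.
#' @export
lmm_assoc <- function(y, geno, K, snps = NULL, alpha = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  n <- length(y)
  if (nrow(d) != n) stop("samples in y and genotypes disagree")
  if (n < 30L) warning("fewer than 30 samples; mixed-model estimates are fragile")
  if (!is.null(snps)) d <- d[, colnames(d) %in% snps, drop = FALSE]
  for (j in seq_len(ncol(d))) {
    mj <- is.na(d[, j])
    if (any(mj)) d[mj, j] <- mean(d[, j], na.rm = TRUE)
  }
  rot <- .lmm_null_rotation(y, K)
  Xs <- crossprod(rot$U, d)
  res <- .gls_scan(rot, Xs)
  res$p[is.na(res$p)] <- 1  # monomorphic columns
  info <- geno$snp_info[match(colnames(d), geno$snp_info$snp_id), , drop = FALSE]
  tab <- data.frame(snp_id = colnames(d), chrom = info$chrom, pos = info$pos,
                    maf = snp_maf(d), beta = res$beta, se = res$se, p = res$p,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, model = "LMM", h2 = rot$h2,
                 lambda_gc = if (nrow(tab) >= 100L) genomic_inflation(tab$p) else NA_real_,
                 thresholds = bonferroni_thresholds(nrow(tab), alpha),
                 n_used = n),
            class = "assoc_result")
}

#' Per-SNP general-linear-model association
#'
#' Simple linear regression of a trait on each SNP's dosage (no fixed
#' covariates), with a t-test p-value. Monomorphic SNPs get `p = 1` and are
#' flagged. The customary screen keeps SNPs with `p < 0.05`.
#'
#' @param trait Length-n phenotype vector.
#' @param geno A [genotype_matrix()].
#' @param snps Optional character vector restricting the scan.
#' @return List of class `"assoc_result"` with `table` (adds `monomorphic`),
#'   `model = "GLM"`, `lambda_gc` (when >= 100 SNPs), `thresholds`, `n_used`.
#' @export
glm_assoc <- function(trait, geno, snps = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  keep <- !is.na(trait)
  d <- d[keep, , drop = FALSE]
  y <- trait[keep]
  if (!is.null(snps)) d <- d[, colnames(d) %in% snps, drop = FALSE]
  n <- length(y)
  beta <- se <- rep(NA_real_, ncol(d))
  p <- rep(1, ncol(d))
  mono <- logical(ncol(d))
  yc <- y - mean(y)
  for (j in seq_len(ncol(d))) {
    xj <- d[, j]
    mj <- is.na(xj)
    if (any(mj)) xj[mj] <- mean(xj, na.rm = TRUE)
    vx <- sum((xj - mean(xj))^2)
    if (vx == 0) { mono[j] <- TRUE; next }
    b <- sum((xj - mean(xj)) * yc) / vx
    r <- yc - b * (xj - mean(xj))
    s2 <- sum(r^2) / (n - 2L)
    se[j] <- sqrt(s2 / vx)
    beta[j] <- b
    p[j] <- 2 * pt(abs(b / se[j]), df = n - 2L, lower.tail = FALSE)
  }
  info <- geno$snp_info[match(colnames(d), geno$snp_info$snp_id), , drop = FALSE]
  tab <- data.frame(snp_id = colnames(d), chrom = info$chrom, pos = info$pos,
                    maf = snp_maf(d), beta = beta, se = se, p = p,
                    monomorphic = mono, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, model = "GLM",
                 lambda_gc = if (nrow(tab) >= 100L) genomic_inflation(tab$p) else NA_real_,
                 thresholds = bonferroni_thresholds(nrow(tab)), n_used = n),
            class = "assoc_result")
}

#' Genomic inflation factor
#'
#' \eqn{\lambda_{GC}} = median of the association chi-square statistics
#' (1 df, from upper-tail p-values) divided by 0.4549364, the null median
#' of a 1-df chi-square. Values near 1 indicate no stratification.
#'
#' @param p_values At least 100 p-values.
#' @return The inflation factor.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) < 100L) stop("need at least 100 p-values")
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Bonferroni significance thresholds
#'
#' Genome-wide threshold `alpha / n_snps` and the suggestive threshold
#' `1 / n_snps`.
#'
#' @param n_snps Number of tests (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `genomewide` and `suggestive`.
#' @export
bonferroni_thresholds <- function(n_snps, alpha = 0.05) {
  stopifnot(n_snps >= 1)
  list(genomewide = alpha / n_snps, suggestive = 1 / n_snps)
}

#' Kruskal-Wallis test across the three genotype classes
#'
#' Rank test of a phenotype (or expression) across dosage groups 0/1/2,
#' with tie correction, referred to chi-square with (groups - 1) df.
#'
#' @param values Numeric vector.
#' @param dosages Matching dosage vector in `{0, 1, 2}` (NA dropped).
#' @return List with `H`, `df`, `p`, `group_sizes`.
#' @export
genotype_group_test <- function(values, dosages) {
  keep <- !is.na(values) & !is.na(dosages)
  v <- values[keep]
  g <- factor(dosages[keep], levels = c(0, 1, 2))
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two genotype classes")
  if (length(unique(v)) == 1L)  # fully tied: H degenerates to 0
    return(list(H = 0, df = nlevels(g) - 1L, p = 1,
                group_sizes = as.integer(table(g))))
  kt <- kruskal.test(v, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, group_sizes = as.integer(table(g)))
}

#' Spearman correlations among carcass traits
#'
#' Pairwise-complete Spearman correlation matrix over the trait columns of
#' a phenotype table.
#'
#' @param pheno data.frame with `sample_id` plus trait columns.
#' @param traits Trait columns to use (default the four carcass traits).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(pheno, traits = c("LW", "DW", "EW", "BMW")) {
  traits <- intersect(traits, names(pheno))
  m <- as.matrix(pheno[, traits, drop = FALSE])
  cor(m, use = "pairwise.complete.obs", method = "spearman")
}

#' SNPs within a gene region, promoter included
#'
#' Keeps SNPs on the gene's chromosome with 1-based positions inside the
#' gene body extended by `promoter_pad` upstream of the transcription start
#' (`[start - pad, end]` on the + strand, `[start, end + pad]` on the -
#' strand).
#'
#' @param geno A [genotype_matrix()].
#' @param locus List with `chrom`, `start`, `end`, `strand` ("+"/"-").
#' @param promoter_pad Upstream pad in bp (default 2000).
#' @return Character vector of SNP ids.
#' @export
extract_gene_region_snps <- function(geno, locus, promoter_pad = 2000) {
  stopifnot(inherits(geno, "genotype_matrix"))
  si <- geno$snp_info
  if (!locus$chrom %in% si$chrom) stop("unknown chromosome: ", locus$chrom)
  if (identical(locus$strand, "-")) {
    lo <- locus$start; hi <- locus$end + promoter_pad
  } else {
    lo <- locus$start - promoter_pad; hi <- locus$end
  }
  si$snp_id[si$chrom == locus$chrom & si$pos >= lo & si$pos <= hi]
}
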