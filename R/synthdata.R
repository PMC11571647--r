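#' Configuration for the synthetic expression/genotype/phenotype generator
#'
#' Bundles every knob of the generator into one validated object. The
#' defaults emulate the reference study's conditions at desk scale: a few
#' hundred birds, a latent-factor module structure in expression, traits
#' built from causal gene expression under the linear model
#' \eqn{y = \mu 1 + \sum_i X_i b_i + e}, and one or more cis-eQTLs driving a
#' focal gene.
#'
#' @param n_samples Number of samples (birds).
#' @param m_genes Number of genes.
#' @param p_snps Number of biallelic SNPs.
#' @param n_causal_genes Number of genes with non-zero trait effects.
#' @param causal_effect_sizes Effect sizes, recycled over causal genes, in
#'   units of phenotypic SD per expression SD.
#' @param trait_heritability_expr Fraction of trait variance explained by
#'   the causal expression term, in `[0, 1]`; the residual variance is solved
#'   analytically from the realized genetic variance. `NA` switches to
#'   absolute-effect mode: the residual has unit variance, so effect sizes
#'   act directly in phenotypic-SD units and the explained fraction follows
#'   from them (needed when comparing power across effect sizes, where
#'   fixing the explained fraction would cancel the effect size out).
#' @param n_modules Number of latent co-expression modules.
#' @param module_sizes Integer vector of module sizes; must sum to at most
#'   `m_genes`.
#' @param module_factor_loading Loading of module genes on their latent
#'   factor, in `(0, 1)`; within-module latent correlation is its square.
#' @param nb_dispersion Shared negative-binomial dispersion of counts
#'   (`size = 1/dispersion`).
#' @param size_factor_log_sd SD of log sample-specific size factors.
#' @param maf_range Interval within `(0, 0.5]` from which per-SNP minor
#'   allele frequencies are drawn uniformly.
#' @param n_cis_eqtl Number of planted cis-eQTL SNPs for the focal gene.
#' @param cis_eqtl_beta Per-allele effect of each cis-eQTL on the focal
#'   gene's latent expression (expression SD per allele).
#' @param latent_log_sd Log-scale amplitude translating one latent
#'   expression SD into log count-mean units.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   gene baseline count means.
#' @param shared_causal_fraction Fraction of causal genes shared by all four
#'   traits (the remainder act on EW only), which induces positive pairwise
#'   trait correlations.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 350L, m_genes = 1000L, p_snps = 500L,
                       n_causal_genes = 10L, causal_effect_sizes = 0.5,
                       trait_heritability_expr = 0.5,
                       n_modules = 4L, module_sizes = rep(60L, n_modules),
                       module_factor_loading = 0.8, nb_dispersion = 0.1,
                       size_factor_log_sd = 0.2, maf_range = c(0.05, 0.5),
                       n_cis_eqtl = 1L, cis_eqtl_beta = 0.8,
                       latent_log_sd = 1.0,
                       base_mean_meanlog = log(100), base_mean_sdlog = 1.0,
                       shared_causal_fraction = 0.5, seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), m_genes = as.integer(m_genes),
    p_snps = as.integer(p_snps), n_causal_genes = as.integer(n_causal_genes),
    causal_effect_sizes = as.numeric(causal_effect_sizes),
    trait_heritability_expr = trait_heritability_expr,
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    module_factor_loading = module_factor_loading,
    nb_dispersion = nb_dispersion, size_factor_log_sd = size_factor_log_sd,
    maf_range = as.numeric(maf_range), n_cis_eqtl = as.integer(n_cis_eqtl),
    cis_eqtl_beta = cis_eqtl_beta, latent_log_sd = latent_log_sd,
    base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
    shared_causal_fraction = shared_causal_fraction, seed = as.integer(seed)
  )
  if (cfg$n_samples < 2L) stop("n_samples must be at least 2")
  if (cfg$n_modules != length(cfg$module_sizes))
    stop("module_sizes must have length n_modules")
  if (sum(cfg$module_sizes) > cfg$m_genes)
    stop("sum(module_sizes) exceeds m_genes")
  if (cfg$n_causal_genes > cfg$m_genes)
    stop("n_causal_genes exceeds m_genes")
  h <- cfg$trait_heritability_expr
  if (!is.na(h) && (h < 0 || h > 1))
    stop("trait_heritability_expr must lie in [0, 1] (or NA for absolute effects)")
  if (!is.na(h) && h > 0 && cfg$n_causal_genes == 0L)
    stop("positive trait_heritability_expr requires at least one causal gene")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (cfg$module_factor_loading <= 0 || cfg$module_factor_loading >= 1)
    stop("module_factor_loading must lie in (0, 1)")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$n_cis_eqtl > cfg$p_snps) stop("n_cis_eqtl exceeds p_snps")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-block seeds derived from the master seed. Blocks are
# drawn in a fixed, documented order (genotypes, latent expression, counts,
# traits) so adding a later block never perturbs an earlier one.
.block_seed <- function(seed, block) {
  as.integer((as.double(seed) * 7919 + block * 104729) %% 2147483646L) + 1L
}

.gram_scale <- function() {
  ref <- carcass_trait_reference()
  list(mean = setNames(ref$mean, ref$trait), sd = setNames(ref$sd, ref$trait))
}

.simulate_core <- function(config, null = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples; m <- config$m_genes; p <- config$p_snps
  gene_ids <- sprintf("gene_%04d", seq_len(m))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  snp_ids <- sprintf("snp_%05d", seq_len(p))

  ## block 1: genotypes (HWE, independent SNPs, MAF ~ U(maf_range))
  set.seed(.block_seed(config$seed, 1L))
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), nrow = n, ncol = p,
                   dimnames = list(sample_ids, snp_ids))
  ## focal gene body on chr1 at 5,000-9,000 (+ strand); planted eQTLs sit
  ## inside it, background SNPs are spaced downstream
  focal_locus <- list(chrom = "chr1", start = 5000L, end = 9000L, strand = "+")
  pos <- integer(p)
  k_eqtl <- config$n_cis_eqtl
  if (k_eqtl > 0L) pos[seq_len(k_eqtl)] <- 6000L + 200L * (seq_len(k_eqtl) - 1L)
  if (p > k_eqtl) pos[(k_eqtl + 1L):p] <- 20000L + 10000L * seq_len(p - k_eqtl)
  snp_info <- data.frame(snp_id = snp_ids, chrom = "chr1", pos = pos,
                         ref = "A", alt = "G", maf_drawn = maf,
                         stringsAsFactors = FALSE)
  geno <- genotype_matrix(dosage, snp_info)

  ## block 2: latent expression (module factors + noise + cis-eQTL shift)
  set.seed(.block_seed(config$seed, 2L))
  module_of <- integer(m)
  if (config$n_modules > 0L) {
    ends <- cumsum(config$module_sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in seq_len(config$n_modules)) module_of[starts[k]:ends[k]] <- k
  }
  fac <- matrix(rnorm(n * max(config$n_modules, 1L)), nrow = n)
  noise <- matrix(rnorm(m * n), nrow = m, ncol = n)
  lam <- config$module_factor_loading
  latent <- noise
  for (g in seq_len(m)) {
    if (module_of[g] > 0L)
      latent[g, ] <- lam * fac[, module_of[g]] + sqrt(1 - lam^2) * noise[g, ]
  }
  focal <- 1L  # first gene; first module gene when modules exist
  eqtl_ids <- character(0)
  eqtl_betas <- numeric(0)
  if (!null && k_eqtl > 0L && config$cis_eqtl_beta != 0) {
    eqtl_ids <- snp_ids[seq_len(k_eqtl)]
    eqtl_betas <- setNames(rep(config$cis_eqtl_beta, k_eqtl), eqtl_ids)
    for (j in seq_len(k_eqtl))
      latent[focal, ] <- latent[focal, ] +
        config$cis_eqtl_beta * (dosage[, j] - 2 * maf[j])
  }
  dimnames(latent) <- list(gene_ids, sample_ids)

  ## block 3: counts = NB(mean = size_factor * base_mean * exp(tau * z))
  set.seed(.block_seed(config$seed, 3L))
  base_mean <- rlnorm(m, config$base_mean_meanlog, config$base_mean_sdlog)
  sf_raw <- exp(rnorm(n, 0, config$size_factor_log_sd))
  sf <- sf_raw / exp(mean(log(sf_raw)))
  mu <- (base_mean %o% sf) * exp(config$latent_log_sd * latent)
  counts <- matrix(rnbinom(m * n, mu = mu, size = 1 / config$nb_dispersion),
                   nrow = m, ncol = n, dimnames = list(gene_ids, sample_ids))

  ## block 4: traits on the gram scale of the reference population
  set.seed(.block_seed(config$seed, 4L))
  gs <- .gram_scale()
  traits <- c("LW", "DW", "EW", "BMW")
  nc <- if (null) 0L else config$n_causal_genes
  causal_idx <- integer(0)
  b <- numeric(0)
  trait_causal <- setNames(vector("list", 4L), traits)
  if (nc > 0L) {
    nonmod <- which(module_of == 0L)
    pool <- setdiff(c(focal, nonmod, seq_len(m)), integer(0))
    causal_idx <- unique(pool)[seq_len(nc)]
    b <- setNames(rep_len(config$causal_effect_sizes, nc), gene_ids[causal_idx])
    n_core <- max(1L, ceiling(nc * config$shared_causal_fraction))
    core <- causal_idx[seq_len(n_core)]
    trait_causal <- list(LW = gene_ids[core], DW = gene_ids[core],
                         EW = gene_ids[causal_idx], BMW = gene_ids[core])
  }
  zstd <- latent
  if (m > 0L) {
    mu_g <- rowMeans(latent)
    sd_g <- apply(latent, 1L, sd)
    zstd <- (latent - mu_g) / sd_g
  }
  h <- if (null) 0 else config$trait_heritability_expr
  pheno <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (tr in traits) {
    ids <- trait_causal[[tr]]
    if ((is.na(h) || h > 0) && length(ids) > 0L) {
      g <- drop(crossprod(zstd[ids, , drop = FALSE], b[ids]))
      if (is.na(h)) {           # absolute-effect mode: unit residual
        raw <- g + rnorm(n)
      } else {
        vg <- var(g)
        raw <- if (h >= 1) g else g + rnorm(n, 0, sqrt(vg * (1 - h) / h))
      }
    } else {
      raw <- rnorm(n)
    }
    pheno[[tr]] <- gs$mean[tr] + gs$sd[tr] * (raw - mean(raw)) / sd(raw)
  }

  truth <- list(
    causal_gene_ids = gene_ids[causal_idx],
    causal_effects = b,
    trait_causal = trait_causal,
    module_assignment_true = setNames(module_of, gene_ids),
    eqtl_snp_ids = eqtl_ids,
    eqtl_target_gene = if (length(eqtl_ids)) gene_ids[focal] else NA_character_,
    eqtl_betas = eqtl_betas,
    focal_gene = gene_ids[focal],
    focal_gene_locus = focal_locus,
    latent = latent,
    size_factors_true = setNames(sf, sample_ids),
    maf_drawn = setNames(maf, snp_ids)
  )
  structure(list(counts = counts, pheno = pheno, geno = geno, truth = truth,
                 config = config),
            class = "sim_data")
}

#' Simulate a full synthetic dataset with planted ground truth
#'
#' Generates, in a fixed block order keyed by `config$seed`: (1) independent
#' Hardy-Weinberg genotypes with uniform allele-frequency spectrum, (2)
#' latent gene expression with module factor structure and a cis-eQTL dosage
#' shift on the focal gene, (3) negative-binomial counts with log-normal
#' baseline means and sample size factors, and (4) four positively
#' correlated carcass traits built from the standardized latent expression
#' of the causal genes, with the residual variance solved so the causal term
#' explains `trait_heritability_expr` of the trait variance.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_data"` with elements `counts` (gene x
#'   sample integer matrix), `pheno` (data.frame `sample_id`, `LW`, `DW`,
#'   `EW`, `BMW`, grams), `geno` (a [genotype_matrix()]), `truth` (planted
#'   ground truth: causal genes and effects, true module labels, eQTL SNPs
#'   and betas, focal gene and locus, latent expression, true size factors)
#'   and `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 40, m_genes = 50,
#'                                    p_snps = 20, module_sizes = c(10, 10),
#'                                    n_modules = 2, seed = 7))
#' dim(sim$counts)
simulate_dataset <- function(config) .simulate_core(config, null = FALSE)

#' Simulate a null dataset (no causal genes, no eQTL effects)
#'
#' Identical machinery to [simulate_dataset()] with every gene effect and
#' every eQTL beta forced to zero, so traits are pure noise around the
#' reference gram scale. Used by the type-I-error simulation harness.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()]; `truth$causal_gene_ids` is empty.
#' @export
simulate_null <- function(config) .simulate_core(config, null = TRUE)

#' Write a simulated dataset to standard on-disk formats
#'
#' Emits a counts TSV (gene rows), a phenotype CSV (`sample_id`, `LW`, `DW`,
#' `EW`, `BMW`), a minimal VCF v4.2 with GT-only genotype records, and the
#' planted truth as JSON (latent matrix omitted).
#'
#' @param sim A `"sim_data"` object.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             pheno = file.path(dir, "phenotypes.csv"),
             vcf = file.path(dir, "genotypes.vcf"),
             truth = file.path(dir, "truth.json"))
  write_counts(sim$counts, paths["counts"])
  utils::write.csv(sim$pheno, paths["pheno"], row.names = FALSE, quote = FALSE)
  write_vcf(sim$geno, paths["vcf"])
  truth <- sim$truth
  truth$latent <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
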