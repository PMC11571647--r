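test_that("GRM is symmetric with unit-scale diagonal and flags relatedness", {
  s <- small_sim(seed = 34, n = 100, m = 10, p = 300)
  K <- build_grm(s$geno)
  expect_true(isSymmetric(K))
  expect_lt(abs(mean(diag(K)) - 1), 0.1)
  expect_lt(abs(mean(K[upper.tri(K)])), 0.05)
  # duplicated sample: its cross-entry matches the diagonal scale
  d2 <- rbind(s$geno$dosage, dup = s$geno$dosage[1, ])
  g2 <- genotype_matrix(d2, s$geno$snp_info)
  K2 <- build_grm(g2)
  expect_lt(abs(K2["dup", "sample_001"] - K2["sample_001", "sample_001"]), 1e-8)
})

test_that("identity-kinship mixed model equals the per-SNP GLM", {
  s <- small_sim(seed = 35, n = 90, m = 10, p = 40)
  y <- standardize_vector(s$pheno$EW)
  lm_res <- lmm_assoc(y, s$geno, diag(90))
  glm_res <- glm_assoc(s$pheno$EW, s$geno)
  # same betas up to the trait standardization scale
  sc <- sd(s$pheno$EW)
  keep <- !glm_res$table$monomorphic
  expect_lt(max(abs(lm_res$table$beta[keep] * sc - glm_res$table$beta[keep])),
            1e-6)
  expect_lt(max(abs(lm_res$table$p[keep] - glm_res$table$p[keep])), 1e-5)
})

test_that("planted cis-eQTL dominates the expression scan", {
  s <- simulate_dataset(sim_config(n_samples = 300, m_genes = 40, p_snps = 150,
                                   n_cis_eqtl = 1, cis_eqtl_beta = 0.8,
                                   n_modules = 1, module_sizes = 20L,
                                   seed = 36))
  e <- norm_log_expr(s)
  K <- build_grm(s$geno)
  res <- lmm_assoc(standardize_vector(e[s$truth$focal_gene, ]), s$geno, K)
  expect_identical(res$table$snp_id[which.min(res$table$p)],
                   s$truth$eqtl_snp_ids)
  expect_lt(min(res$table$p), res$thresholds$genomewide)
})

test_that("genomic inflation is calibrated", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1, tolerance = 1e-12)
  set.seed(37)
  p <- runif(1e5)
  expect_lt(abs(genomic_inflation(p) - 1), 0.02)
  # scale equivariance: doubling every chi-square statistic doubles lambda
  q <- qchisq(p[1:1000], 1, lower.tail = FALSE)
  p2 <- pchisq(2 * q, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), 2 * genomic_inflation(p[1:1000]),
               tolerance = 1e-10)
  expect_error(genomic_inflation(runif(50)), "100")
})

test_that("Bonferroni thresholds follow alpha/n and 1/n", {
  th <- bonferroni_thresholds(100)
  expect_equal(th$genomewide, 5e-4)
  expect_equal(th$suggestive, 1e-2)
  th1 <- bonferroni_thresholds(1)
  expect_equal(th1$genomewide, 0.05)
  expect_equal(th1$suggestive, 1)
  ns <- c(10, 100, 1000, 1e6)
  gw <- vapply(ns, function(n) bonferroni_thresholds(n)$genomewide, 1)
  expect_true(all(diff(gw) < 0))
})

test_that("per-SNP GLM finds exact linear signals and stays calibrated on permuted traits", {
  s <- small_sim(seed = 38, n = 120, m = 10, p = 200)
  trait <- 2 * s$geno$dosage[, 5] + rnorm(120, 0, 1e-8)
  res <- glm_assoc(trait, s$geno)
  expect_equal(res$table$beta[5], 2, tolerance = 1e-6)
  expect_lt(res$table$p[5], 1e-20)
  # permutation oracle: ~5% of SNPs significant for a shuffled trait
  hits <- integer(6)
  for (r in 1:6) {
    set.seed(1000 + r)
    perm <- sample(s$pheno$EW)
    hits[r] <- sum(glm_assoc(perm, s$geno)$table$p < 0.05)
  }
  rate <- sum(hits) / (6 * 200)
  ci <- 3 * sqrt(0.05 * 0.95 / (6 * 200))
  expect_lt(abs(rate - 0.05), ci + 0.01)
  # monomorphic SNPs are flagged with p = 1
  dos <- cbind(mono = rep(0, 20), ok = rbinom(20, 2, 0.4))
  rownames(dos) <- paste0("s", 1:20)
  info <- data.frame(snp_id = c("mono", "ok"), chrom = "chr1", pos = c(10, 20),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  r2 <- glm_assoc(rnorm(20), genotype_matrix(dos, info))
  expect_true(r2$table$monomorphic[1])
  expect_equal(r2$table$p[1], 1)
})

test_that("Kruskal-Wallis genotype test matches hand ranks and is rank-invariant", {
  # groups {1,2}, {3,4}, {5,6}: H = 32/7
  v <- c(1, 2, 3, 4, 5, 6)
  d <- c(0, 0, 1, 1, 2, 2)
  kt <- genotype_group_test(v, d)
  expect_equal(kt$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kt$df, 2)
  expect_lt(abs(kt$p - 0.102), 5e-3)
  # all equal values: tie-corrected H degenerates to 0
  kt0 <- genotype_group_test(rep(4, 6), d)
  expect_equal(kt0$H, 0)
  expect_equal(kt0$p, 1)
  # invariance under strictly monotone transforms
  kt2 <- genotype_group_test(exp(v), d)
  expect_equal(kt$H, kt2$H, tolerance = 1e-12)
  expect_error(genotype_group_test(v, rep(1, 6)), "two genotype")
})

test_that("trait correlations are Spearman, symmetric, monotone-invariant", {
  set.seed(39)
  ph <- data.frame(sample_id = paste0("s", 1:300),
                   LW = rnorm(300), DW = rnorm(300))
  ph$EW <- ph$LW^3          # monotone transform
  ph$BMW <- rnorm(300)
  r <- trait_correlations(ph)
  expect_equal(r["LW", "EW"], 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_lt(abs(r["LW", "BMW"]), 0.2)
  ph$LW[5] <- NA            # pairwise-complete handling
  expect_false(anyNA(trait_correlations(ph)))
})

test_that("gene-region SNP extraction respects strand-specific promoter pads", {
  dos <- matrix(rbinom(4 * 10, 2, 0.3), nrow = 10)
  rownames(dos) <- paste0("s", 1:10)
  info <- data.frame(snp_id = paste0("rs", 1:4), chrom = "chr2",
                     pos = c(900L, 1500L, 3500L, 4200L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  colnames(dos) <- info$snp_id
  g <- genotype_matrix(dos, info)
  plus <- list(chrom = "chr2", start = 3000L, end = 4000L, strand = "+")
  expect_setequal(extract_gene_region_snps(g, plus, 2000), c("rs2", "rs3"))
  expect_setequal(extract_gene_region_snps(g, plus, 0), "rs3")
  minus <- list(chrom = "chr2", start = 3000L, end = 4000L, strand = "-")
  expect_setequal(extract_gene_region_snps(g, minus, 2000), c("rs3", "rs4"))
  expect_error(extract_gene_region_snps(g, list(chrom = "chrZ", start = 1,
                                                end = 10, strand = "+")),
               "chromosome")
})
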