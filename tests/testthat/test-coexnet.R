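test_that("adjacency powers correlations with the chosen sign convention", {
  cc <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(adjacency_matrix(cc, 6)[1, 2], 0.5^6)
  cc2 <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(adjacency_matrix(cc2, 6)[1, 2], 0.5^6)   # unsigned folds sign
  expect_equal(adjacency_matrix(cc2, 6, "signed")[1, 2], 0.25^6)
  expect_equal(adjacency_matrix(cc, 1)[1, 2], 0.5)
  expect_error(adjacency_matrix(cc, 0.5), "beta")
})

test_that("TOM matches hand algebra and a brute-force triple loop", {
  # 3 nodes, all off-diagonal a: TOM = (a^2 + a) / (a + 1) = a
  for (a in c(0.2, 0.5, 0.9)) {
    A <- matrix(a, 3, 3); diag(A) <- 1
    tom <- tom_similarity(A)
    expect_equal(tom[1, 2], a, tolerance = 1e-12)
  }
  # isolated node: TOM to it is 0
  A <- matrix(0.4, 4, 4); diag(A) <- 1
  A[4, 1:3] <- A[1:3, 4] <- 0
  expect_equal(unname(tom_similarity(A)[4, 1:3]), rep(0, 3))
  # brute-force oracle on a random symmetric 15 x 15 adjacency
  set.seed(20)
  R <- matrix(runif(225), 15)
  A <- (R + t(R)) / 2; diag(A) <- 1
  tom <- tom_similarity(A)
  k <- rowSums(A) - 1
  brute <- matrix(1, 15, 15)
  for (i in 1:15) for (j in 1:15) if (i != j) {
    num <- sum(A[i, -c(i, j)] * A[-c(i, j), j]) + A[i, j]
    brute[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  expect_lt(max(abs(tom - brute)), 1e-12)
  expect_true(isSymmetric(tom, tol = 1e-12))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("planted blocks are detected as modules; noise stays unassigned", {
  e <- block_expr(c(60, 60), n = 150, rho = 0.8, seed = 21)
  A <- adjacency_matrix(cor(t(e)), 6)
  lab <- detect_modules(1 - tom_similarity(A), min_module_size = 50)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  truth <- rep(1:2, each = 60)
  expect_gte(mclust::adjustedRandIndex(lab, truth), 0.95)
  # determinism
  lab2 <- detect_modules(1 - tom_similarity(A), min_module_size = 50)
  expect_identical(lab, lab2)
  # pure noise: nearly everything unassigned
  en <- block_expr(integer(0), n = 100, n_noise = 200, seed = 22)
  An <- adjacency_matrix(cor(t(en)), 6)
  labn <- detect_modules(1 - tom_similarity(An), min_module_size = 50)
  expect_gte(mean(labn == 0), 0.95)
  # fewer genes than min_module_size: all unassigned with a warning
  expect_warning(lab3 <- detect_modules(matrix(0.5, 10, 10), 50), "unassigned")
  expect_true(all(lab3 == 0))
})

test_that("module eigengenes are unit-norm, sign-aligned first PCs", {
  e <- block_expr(c(30, 30), n = 80, rho = 0.9, seed = 23)
  lab <- setNames(rep(1:2, each = 30), rownames(e))
  E <- module_eigengenes(e, lab)
  expect_equal(dim(E), c(2L, 80L))
  expect_equal(unname(sqrt(rowSums(E^2))), c(1, 1), tolerance = 1e-12)
  for (k in 1:2) {
    sub <- standardize_rows(e[lab == k, ])
    expect_gt(cor(E[k, ], colMeans(sub)), 0)
    expect_gt(abs(cor(E[k, ], sub[1, ])), 0.8)
  }
  expect_true(all(attr(E, "var_explained") > 0.5))
  # a module of identical standardized genes: |cor| with the shared profile is 1
  shared <- rnorm(40)
  e2 <- rbind(g1 = shared, g2 = 2 * shared + 5, g3 = shared - 3)
  colnames(e2) <- paste0("s", 1:40)
  E2 <- module_eigengenes(e2, setNames(rep(1, 3), rownames(e2)))
  expect_equal(abs(cor(E2[1, ], shared)), 1, tolerance = 1e-10)
})

test_that("modules merge by eigengene correlation with order-independent result", {
  # two modules driven by the same factor (eigengene cor ~0.95) plus an
  # independent third: only the first two merge at cut 0.25
  set.seed(24)
  n <- 120
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, sz, noise) t(sapply(seq_len(sz), function(i)
    f + noise * rnorm(n)))
  e <- rbind(mk(f1, 20, 0.3), mk(f1, 20, 0.3), mk(f2, 20, 0.3))
  rownames(e) <- sprintf("g%03d", 1:60)
  colnames(e) <- sprintf("s%03d", 1:n)
  lab <- setNames(rep(1:3, each = 20), rownames(e))
  merged <- merge_modules(e, lab, cut_height = 0.25)
  expect_equal(length(unique(merged[merged > 0])), 2L)
  expect_equal(length(unique(merged[1:40])), 1L)   # first two joined
  expect_false(merged[1] == merged[41])            # third kept apart
  # order independence: relabelling the input modules gives the same partition
  lab_perm <- setNames(c(rep(2L, 20), rep(3L, 20), rep(1L, 20)), rownames(e))
  merged_perm <- merge_modules(e, lab_perm, cut_height = 0.25)
  expect_equal(mclust::adjustedRandIndex(merged, merged_perm), 1)
  # modestly correlated modules are not merged
  e3 <- block_expr(c(20, 20), n = n, rho = 0.8, seed = 25)
  lab3 <- setNames(rep(1:2, each = 20), rownames(e3))
  expect_equal(length(unique(merge_modules(e3, lab3, 0.25))), 2L)
})

test_that("module-trait statistics use the t transform on n-2 df", {
  e <- block_expr(c(25, 25), n = 60, rho = 0.85, seed = 26)
  lab <- setNames(rep(1:2, each = 25), rownames(e))
  E <- module_eigengenes(e, lab)
  trait <- E[1, ] * 3 + 100
  st <- module_trait_stats(E, data.frame(tr = trait))
  expect_equal(unname(st$r["ME1", 1]), 1, tolerance = 1e-10)
  r <- st$r["ME2", 1]
  tstat <- r * sqrt(58 / (1 - r^2))
  expect_equal(unname(st$p["ME2", 1]),
               2 * pt(abs(tstat), 58, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(module_trait_stats(E[, 1:3], data.frame(tr = trait[1:3])),
               "4 samples")
})

test_that("hub screening applies strict GS and MM thresholds in the target module", {
  e <- block_expr(c(40, 40), n = 100, rho = 0.8, n_noise = 20, seed = 27)
  lab <- setNames(c(rep(1:2, each = 40), rep(0L, 20)), rownames(e))
  E <- module_eigengenes(e, lab)
  trait <- E[1, ] + rnorm(100, 0, 0.05)
  hs <- hub_genes(e, E, lab, trait)
  expect_equal(hs$target_module, 1L)
  expect_true(all(hs$hubs %in% rownames(e)[lab == 1]))
  expect_gt(length(hs$hubs), 0)
  sc <- hs$scores[match(hs$hubs, hs$scores$gene_id), ]
  expect_true(all(sc$GS > 0.2 & sc$MM > 0.6))
  # thresholds are strict: raising gs_min above the max GS empties the set
  expect_length(hub_genes(e, E, lab, trait, gs_min = 1, mm_min = 0.6)$hubs, 0)
  # a gene identical to the trait has GS = 1
  e2 <- rbind(e, hubgene = trait)
  lab2 <- c(lab, hubgene = 1L)
  hs2 <- hub_genes(e2, E, lab2, trait)
  expect_equal(hs2$scores$GS[hs2$scores$gene_id == "hubgene"], 1,
               tolerance = 1e-10)
})

test_that("soft-threshold selection is reproducible and warns without scale-free fit", {
  e <- block_expr(c(30, 30), n = 80, rho = 0.7, n_noise = 140, seed = 28)
  r1 <- suppressWarnings(pick_soft_threshold(e))
  r2 <- suppressWarnings(pick_soft_threshold(e))
  expect_identical(r1$power, r2$power)
  expect_true(r1$power %in% 1:20)
  expect_equal(dim(r1$fit_table), c(20L, 4L))
  # independent noise cannot follow a decaying degree law at the target
  en <- block_expr(integer(0), n = 60, n_noise = 120, seed = 29)
  expect_warning(pick_soft_threshold(en), "best fit")
})

test_that("planted-module recovery through the full network stage", {
  # generator modules -> counts -> normalize -> network -> labels
  ok <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_samples = 300, m_genes = 240, p_snps = 5,
                      n_modules = 4, module_sizes = rep(60, 4),
                      module_factor_loading = 0.8, seed = 800 + s)
    sim <- simulate_dataset(cfg)
    e <- norm_log_expr(sim)
    st <- suppressWarnings(pick_soft_threshold(e))
    A <- adjacency_matrix(cor(t(e)), st$power)
    lab <- detect_modules(1 - tom_similarity(A), 50)
    lab <- merge_modules(e, lab, 0.25)
    tr <- sim$truth$module_assignment_true
    if (mclust::adjustedRandIndex(lab[tr > 0], tr[tr > 0]) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 3)
})
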