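#' Pick the soft-threshold power by the scale-free fit criterion
#'
#' For each candidate power, the weighted adjacency is built, connectivity
#' \eqn{k_i = \sum_{j \ne i} A_{ij}} computed, genes binned into 10
#' equal-width bins of k, and \eqn{\log_{10} p(k)} regressed on
#' \eqn{\log_{10} \bar k} (the WGCNA binning convention). The scale-free
#' fit index is the model R-squared with its sign flipped when the slope is
#' positive, so only a decaying degree law scores well. Powers that push the
#' mean connectivity below 1 are ineligible: as the network empties, the
#' degree law becomes vacuously steep (a high fit index with no structure
#' left to cluster). Among eligible powers the chosen one is the smallest
#' reaching `r2_target`; if none does, a warning is issued and the
#' best-fitting eligible power is used.
#'
#' @param expr Gene x sample expression matrix (normalized/log scale).
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_target Scale-free R-squared target (default 0.85).
#' @param type `"unsigned"` or `"signed"` adjacency.
#' @return List with `power`, `fit_table` (power, r2, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.85,
                                type = c("unsigned", "signed")) {
  type <- match.arg(type)
  stopifnot(is.matrix(expr), nrow(expr) >= 50L)
  cc <- cor(t(expr))
  if (any(!is.finite(cc))) stop("constant gene(s); standardize/filter first")
  r2 <- slope <- meank <- numeric(length(powers))
  for (i in seq_along(powers)) {
    A <- adjacency_matrix(cc, powers[i], type)
    k <- rowSums(A) - 1
    meank[i] <- mean(k)
    sf <- .scale_free_fit(k)
    r2[i] <- sf$r2
    slope[i] <- sf$slope
  }
  fit <- data.frame(power = powers, r2 = r2, slope = slope, mean_k = meank)
  eligible <- meank >= 1
  if (!any(eligible)) eligible <- rep(TRUE, length(powers))
  ok <- which(r2 >= r2_target & eligible)
  if (length(ok)) {
    power <- powers[min(ok)]
  } else {
    cand <- which(eligible)
    power <- powers[cand[which.max(r2[cand])]]
    warning("no eligible power reaches scale-free R^2 >= ", r2_target,
            "; using the best fit with mean connectivity >= 1 (power ",
            power, ", R^2 ", round(r2[powers == power], 3), ")")
  }
  list(power = power, fit_table = fit)
}

# Scale-free topology fit: bin log connectivity into 10 equal-width bins,
# regress log10 frequency on log10 mean connectivity; sign-flip R^2 when
# the slope is positive.
.scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(list(r2 = -Inf, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kbar <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0
  if (sum(use) < 3L) return(list(r2 = -Inf, slope = NA_real_))
  x <- log10(kbar[use])
  y <- log10(freq[use] / sum(freq[use]))
  f <- lm(y ~ x)
  r2 <- summary(f)$r.squared
  sl <- coef(f)[2L]
  list(r2 = if (sl > 0) -r2 else r2, slope = unname(sl))
}

#' Weighted adjacency from a correlation matrix
#'
#' Unsigned: \eqn{A = |r|^\beta}; signed: \eqn{A = ((1 + r)/2)^\beta}.
#' The diagonal is set to 1.
#'
#' @param corr Correlation matrix in `[-1, 1]`.
#' @param beta Soft power (>= 1).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(corr, beta, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) stop("beta must be >= 1")
  A <- if (type == "unsigned") abs(corr)^beta else ((1 + corr) / 2)^beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} A_{iu}A_{uj} + A_{ij}}
#'                      {\min(k_i, k_j) + 1 - A_{ij}}}
#' with \eqn{k_i = \sum_{u \ne i} A_{iu}} and \eqn{TOM_{ii} = 1}: the
#' interconnectedness of two genes' shared network neighbourhoods. The
#' dissimilarity used for clustering is `1 - TOM`.
#'
#' @param A Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("A must be symmetric")
  k <- rowSums(A) - 1
  AA <- A %*% A          # (AA)_ij includes u = i and u = j, each adding A_ij
  num <- AA - 2 * A + A
  denom <- outer(k, k, pmin) + 1 - A
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect modules by hierarchical clustering with a fixed-quantile tree cut
#'
#' Average-linkage clustering of the TOM dissimilarity, cut at a fixed
#' fraction of the top merge height (the deterministic static/"tree"
#' variant of dynamic cutting). Clusters smaller than `min_module_size`
#' fall into the unassigned label 0; surviving modules are renumbered by
#' decreasing size. Unconnected genes merge at dissimilarity essentially 1,
#' so the 0.99 cut detaches them while leaving within-module merges intact.
#'
#' @param dissim Square dissimilarity matrix (1 - TOM).
#' @param min_module_size Minimum genes per module (default 50).
#' @param cut_frac Fraction of the maximum merge height at which to cut
#'   (default 0.99).
#' @return Named integer vector of labels (0 = unassigned).
#' @export
detect_modules <- function(dissim, min_module_size = 50L, cut_frac = 0.99) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  m <- nrow(dissim)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (m < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(setNames(integer(m), ids))
  }
  hc <- hclust(as.dist(dissim), method = "average")
  raw <- cutree(hc, h = cut_frac * max(hc$height))
  sizes <- table(raw)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(m)
  if (length(big)) {
    ord <- big[order(-sizes[as.character(big)], big)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  setNames(labels, ids)
}

#' Module eigengenes
#'
#' Per module, the first principal component of the standardized member
#' gene x sample submatrix, as a unit-norm sample vector whose sign is
#' aligned so it correlates positively with the mean member expression.
#'
#' @param expr Gene x sample expression matrix.
#' @param labels Module labels from [detect_modules()] (0 ignored).
#' @return Module x sample matrix of unit-norm eigengenes, with an
#'   attribute `var_explained`.
#' @export
module_eigengenes <- function(expr, labels) {
  stopifnot(is.matrix(expr), length(labels) == nrow(expr))
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned modules")
  E <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
              dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    sub <- expr[labels == mods[i], , drop = FALSE]
    if (nrow(sub) < 2L) stop("module ", mods[i], " has fewer than 2 genes")
    subs <- standardize_rows(sub)
    sv <- svd(subs, nu = 0, nv = 1)
    e <- sv$v[, 1L]
    if (cor(e, colMeans(subs)) < 0) e <- -e
    E[i, ] <- e
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(E, "var_explained") <- setNames(ve, rownames(E))
  E
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor` is below `cut_height`, recomputing eigengenes
#' after every merge, until no pair qualifies. Labels are renumbered by
#' decreasing size at the end.
#'
#' @param expr Gene x sample expression matrix.
#' @param labels Module labels (0 = unassigned, left untouched).
#' @param cut_height Eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. correlation above 0.75).
#' @return Named integer label vector after merging.
#' @export
merge_modules <- function(expr, labels, cut_height = 0.25) {
  stopifnot(length(labels) == nrow(expr))
  labels <- setNames(as.integer(labels), names(labels))
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2L) break
    E <- module_eigengenes(expr, labels)
    cc <- cor(t(E))
    diss <- 1 - cc
    diag(diss) <- Inf
    i <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[i[1L], i[2L]] >= cut_height) break
    from <- mods[max(i)]; into <- mods[min(i)]
    labels[labels == from] <- into
  }
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods)) {
    sizes <- vapply(mods, function(k) sum(labels == k), integer(1))
    new <- integer(length(labels))
    ord <- mods[order(-sizes, mods)]
    for (i in seq_along(ord)) new[labels == ord[i]] <- i
    labels <- setNames(new, names(labels))
  }
  labels
}

#' Module-trait correlation statistics
#'
#' Pearson correlation of every module eigengene with every trait, with
#' two-sided p-values from the t transform on n - 2 degrees of freedom.
#'
#' @param eigengenes Module x sample matrix from [module_eigengenes()].
#' @param traits data.frame or matrix of traits (samples in rows, aligned
#'   with the eigengene columns).
#' @return List with matrices `r` and `p` (modules x traits).
#' @export
module_trait_stats <- function(eigengenes, traits) {
  tm <- as.matrix(traits)
  n <- ncol(eigengenes)
  if (nrow(tm) != n) stop("samples in eigengenes and traits disagree")
  if (n < 4L) stop("need at least 4 samples")
  r <- cor(t(eigengenes), tm, use = "pairwise.complete.obs")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

#' Hub-gene screening by gene significance and module membership
#'
#' GS is the absolute Pearson correlation of a gene with the trait; MM the
#' absolute correlation with its own module's eigengene. Hubs are the genes
#' of the target module — by default the module with the largest absolute
#' module-trait correlation — with `GS > gs_min` and `MM > mm_min` (strict
#' inequalities).
#'
#' @param expr Gene x sample expression matrix.
#' @param eigengenes Module x sample matrix.
#' @param labels Per-gene module labels.
#' @param trait Length-`ncol(expr)` phenotype vector.
#' @param gs_min,mm_min Strict lower thresholds (defaults 0.2 and 0.6).
#' @param module Target module index; `NULL` picks the top trait-correlated
#'   module.
#' @return List of class `"hub_scores"`: `scores` (gene_id, module, GS, MM),
#'   `hubs`, `target_module`.
#' @export
hub_genes <- function(expr, eigengenes, labels, trait, gs_min = 0.2,
                      mm_min = 0.6, module = NULL) {
  stopifnot(is.matrix(expr), length(trait) == ncol(expr))
  keep <- !is.na(trait)
  mt <- module_trait_stats(eigengenes[, keep, drop = FALSE],
                           matrix(trait[keep], ncol = 1))
  mods <- as.integer(sub("^ME", "", rownames(eigengenes)))
  if (is.null(module)) module <- mods[which.max(abs(mt$r[, 1L]))]
  gs <- abs(apply(expr[, keep, drop = FALSE], 1L, cor, y = trait[keep]))
  mm <- rep(NA_real_, nrow(expr))
  for (k in mods) {
    in_k <- labels == k
    mm[in_k] <- abs(cor(t(expr[in_k, , drop = FALSE]),
                        eigengenes[paste0("ME", k), ]))
  }
  scores <- data.frame(gene_id = rownames(expr), module = as.integer(labels),
                       GS = gs, MM = mm, row.names = NULL,
                       stringsAsFactors = FALSE)
  hubs <- scores$gene_id[scores$module == module &
                           !is.na(scores$MM) &
                           scores$GS > gs_min & scores$MM > mm_min]
  structure(list(scores = scores, hubs = hubs, target_module = module),
            class = "hub_scores")
}

#' Run the full co-expression network stage
#'
#' Outlier-sample removal, soft-threshold selection, adjacency, TOM,
#' module detection, eigengene merging, module-trait correlations and hub
#' screening for each trait, in one deterministic pass.
#'
#' @param expr Gene x sample normalized (log-scale) expression matrix.
#' @param pheno Phenotype data.frame aligned by `sample_id` to the columns.
#' @param traits Trait columns to correlate (default the four carcass
#'   traits).
#' @param min_module_size,merge_cut,gs_min,mm_min Stage parameters.
#' @param powers,r2_target Passed to [pick_soft_threshold()].
#' @param type Adjacency type.
#' @return List of class `"network_modules"`: `power`, `scale_free_r2`,
#'   `labels`, `eigengenes`, `module_trait`, `hubs` (per trait), `removed`.
#' @export
run_wgcna <- function(expr, pheno, traits = c("LW", "DW", "EW", "BMW"),
                      min_module_size = 50L, merge_cut = 0.25,
                      gs_min = 0.2, mm_min = 0.6, powers = 1:20,
                      r2_target = 0.85, type = "unsigned") {
  clean <- remove_outlier_samples(expr)
  expr <- clean$expr
  expr <- expr[apply(expr, 1L, sd) > 0, , drop = FALSE]  # constant genes carry no signal
  pheno <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]
  st <- pick_soft_threshold(expr, powers, r2_target, type)
  A <- adjacency_matrix(cor(t(expr)), st$power, type)
  tom <- tom_similarity(A)
  labels <- detect_modules(1 - tom, min_module_size)
  if (any(labels > 0)) labels <- merge_modules(expr, labels, merge_cut)
  E <- module_eigengenes(expr, labels)
  traits <- intersect(traits, names(pheno))
  mt <- module_trait_stats(E, pheno[, traits, drop = FALSE])
  hubs <- lapply(setNames(traits, traits), function(tr)
    hub_genes(expr, E, labels, pheno[[tr]], gs_min, mm_min))
  structure(list(power = st$power,
                 scale_free_r2 = st$fit_table$r2[st$fit_table$power == st$power],
                 fit_table = st$fit_table, labels = labels, eigengenes = E,
                 module_trait = mt, hubs = hubs, removed = clean$removed,
                 n_used = ncol(expr)),
            class = "network_modules")
}
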