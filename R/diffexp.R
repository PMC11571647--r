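#' Split samples into extreme high/low phenotype groups
#'
#' Sorts the non-missing phenotypes and takes the top `n_per_group` samples
#' as the high group and the bottom `n_per_group` as the low group. Ties
#' spanning a group boundary are broken by stable sample-id order, so the
#' split is deterministic.
#'
#' @param pheno Phenotype data.frame with a `sample_id` column.
#' @param trait Trait column name.
#' @param n_per_group Samples per group (default 30).
#' @return List with character vectors `high` and `low` and the trait name.
#' @export
split_high_low <- function(pheno, trait, n_per_group = 30L) {
  stopifnot(trait %in% names(pheno))
  ok <- !is.na(pheno[[trait]])
  if (sum(ok) < 2L * n_per_group)
    stop("need at least ", 2L * n_per_group, " non-missing phenotypes")
  ids <- pheno$sample_id[ok]
  v <- pheno[[trait]][ok]
  ord <- order(v, ids)  # ascending value, ties by sample id
  list(low = ids[ord[seq_len(n_per_group)]],
       high = ids[rev(ord)[seq_len(n_per_group)]],
       trait = trait)
}

#' Differential expression between extreme groups
#'
#' Per gene: fold change `(mean_high + c) / (mean_low + c)` with
#' pseudo-count `c = 1` on normalized counts, and a Welch two-sample t-test
#' on `log2(x + 1)`. A gene is a DEG when the fold change exceeds `fc_min`
#' in either direction and `p < p_max`. Genes with zero variance in both
#' groups get `p = 1` and are flagged.
#'
#' @param norm_expr Normalized gene x sample count matrix.
#' @param groups A [split_high_low()] result (or any list with `high` and
#'   `low` sample ids present in the columns).
#' @param fc_min Fold-change threshold (default 1.5).
#' @param p_max P-value threshold (default 0.05).
#' @param pseudo Pseudo-count stabilizing low-count ratios (default 1).
#' @return data.frame of class `"de_result"`: `gene_id`, `mean_high`,
#'   `mean_low`, `fc`, `log2fc`, `p`, `is_deg`, `zero_var`; group sizes in
#'   attributes.
#' @export
de_test <- function(norm_expr, groups, fc_min = 1.5, p_max = 0.05,
                    pseudo = 1) {
  stopifnot(is.matrix(norm_expr))
  hi <- intersect(groups$high, colnames(norm_expr))
  lo <- intersect(groups$low, colnames(norm_expr))
  if (length(hi) < 2L || length(lo) < 2L)
    stop("both groups need at least 2 samples present in the matrix")
  xh <- norm_expr[, hi, drop = FALSE]
  xl <- norm_expr[, lo, drop = FALSE]
  mh <- rowMeans(xh)
  ml <- rowMeans(xl)
  fc <- (mh + pseudo) / (ml + pseudo)
  lh <- log2(xh + 1)
  ll <- log2(xl + 1)
  vh <- apply(lh, 1L, var)
  vl <- apply(ll, 1L, var)
  zero_var <- vh == 0 & vl == 0
  p <- rep(1, nrow(norm_expr))
  for (g in which(!zero_var))
    p[g] <- tryCatch(t.test(lh[g, ], ll[g, ])$p.value,
                     # both groups constant at different levels: the Welch
                     # statistic degenerates; call the difference certain
                     error = function(e) if (mh[g] != ml[g]) 0 else 1)
  out <- data.frame(gene_id = rownames(norm_expr), mean_high = mh,
                    mean_low = ml, fc = fc, log2fc = log2(fc), p = p,
                    is_deg = (fc > fc_min | fc < 1 / fc_min) & p < p_max,
                    zero_var = zero_var, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "group_sizes") <- c(high = length(hi), low = length(lo))
  class(out) <- c("de_result", "data.frame")
  out
}
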