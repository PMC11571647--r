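# Restricted log-likelihood of the variance-ratio model
#   y = X0 a + g + e,  g ~ N(0, s2*h2*K), e ~ N(0, s2*(1-h2))
# after rotating by the eigenvectors of K. Overall scale s2 is profiled out,
# leaving a 1-D problem in h2. `d` are eigenvalues of K, `ys`/`Xs` the
# rotated response and fixed-effect design.
.reml_ll <- function(h2, d, ys, Xs) {
  n <- length(ys); q <- ncol(Xs)
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  bh <- solve(XtWX, XtWy)
  r <- ys - Xs %*% bh
  rss <- sum(r^2 * w)
  -0.5 * ((n - q) * log(rss / (n - q)) + sum(log(v)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

# REML estimate of h2 on a coarse grid refined by golden-section search.
.reml_h2 <- function(d, ys, Xs, grid_n = 50L) {
  lo <- 1e-4; hi <- 1 - 1e-4
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, .reml_ll, numeric(1), d = d, ys = ys, Xs = Xs)
  i <- which.max(ll)
  a <- grid[max(i - 1L, 1L)]; b <- grid[min(i + 1L, grid_n)]
  opt <- optimize(.reml_ll, c(a, b), d = d, ys = ys, Xs = Xs, maximum = TRUE,
                  tol = 1e-6)
  opt$maximum
}

.check_psd <- function(K, tol = 1e-8) {
  if (!isSymmetric(K, tol = 1e-8)) stop("K must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) stop("K is not positive semidefinite")
  invisible(TRUE)
}

#' Single-predictor linear mixed model with a polygenic random effect
#'
#' Fits \eqn{y = \mu + x b + u + \epsilon} with \eqn{u \sim N(0,
#' \sigma^2_g K)} by eigendecomposing `K`, estimating the heritability-like
#' variance ratio by REML (grid plus golden-section refinement), and
#' testing the fixed effect with a Wald chi-square (1 df). With `K = I` the
#' model collapses to ordinary simple regression. The Wald p-value uses the
#' t reference on n - 2 df, so the collapse is exact.
#'
#' @param x Length-n predictor (e.g. one gene's standardized expression).
#' @param y Length-n response.
#' @param K n x n symmetric PSD covariance of the random effect.
#' @return List: `effect`, `se`, `p`, `h2`, `n`.
#' @export
fit_lmm_gene <- function(x, y, K) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(K) == n, ncol(K) == n)
  .check_psd(K)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, cbind(1, x))
  h2 <- .reml_h2(d, ys, Xs)
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  bh <- solve(XtWX, XtWy)
  r <- ys - Xs %*% bh
  s2 <- sum(r^2 * w) / (n - 2L)
  cov_b <- s2 * solve(XtWX)
  se <- sqrt(cov_b[2L, 2L])
  # Wald test against the t reference on the residual df (the mixed-model
  # association convention); collapses exactly onto the GLM at K = I
  p <- 2 * pt(abs(bh[2L] / se), df = n - 2L, lower.tail = FALSE)
  list(effect = bh[2L], se = se, p = p, h2 = h2, n = n)
}

# Null-model variance components shared across SNPs (EMMAX-style): rotate
# once, estimate h2 under the intercept-only model, then test each
# predictor by GLS at that fixed variance ratio.
.lmm_null_rotation <- function(y, K) {
  .check_psd(K)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  ones <- crossprod(U, matrix(1, length(y), 1))
  h2 <- .reml_h2(d, ys, ones)
  list(U = U, d = d, ys = ys, ones = ones, h2 = h2)
}

.gls_scan <- function(rot, Xs_cols) {
  # Xs_cols: rotated predictors, one column per test
  n <- length(rot$ys)
  w <- 1 / (rot$h2 * rot$d + (1 - rot$h2))
  one <- drop(rot$ones)
  s11 <- sum(w * one * one)
  s1y <- sum(w * one * rot$ys)
  beta <- se <- p <- rep(NA_real_, ncol(Xs_cols))
  for (j in seq_len(ncol(Xs_cols))) {
    xj <- Xs_cols[, j]
    sxx <- sum(w * xj * xj)
    sx1 <- sum(w * xj * one)
    sxy <- sum(w * xj * rot$ys)
    det <- s11 * sxx - sx1^2
    if (det <= 0) next  # collinear with the intercept (monomorphic SNP)
    b2 <- (s11 * sxy - sx1 * s1y) / det
    b1 <- (s1y - sx1 * b2) / s11
    r <- rot$ys - b1 * one - b2 * xj
    s2 <- sum(w * r^2) / (n - 2L)
    v2 <- s2 * s11 / det
    beta[j] <- b2
    se[j] <- sqrt(v2)
    p[j] <- 2 * pt(abs(b2) / sqrt(v2), df = n - 2L, lower.tail = FALSE)
  }
  data.frame(beta = beta, se = se, p = p)
}
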