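test_that("full shrinkage above lambda_max, OLS at lambda zero", {
  X <- std_design(20, 5, seed = 2)
  set.seed(3)
  y <- rnorm(20)
  lmax <- twaspipe:::.lambda_max(X, y, 0.6)
  f <- fit_en(X, y, alpha = 0.6, lambda = lmax * 1.000001)
  expect_true(all(f$beta == 0))
  # normal-equations oracle at lambda = 0 on a full-rank instance
  f0 <- fit_en(X, y, alpha = 0.6, lambda = 0, tol = 1e-10)
  ols <- qr.solve(cbind(1, X), y)
  expect_lt(max(abs(f0$beta - ols[-1])), 1e-8)
  expect_lt(abs(f0$intercept - ols[1]), 1e-8)
})

test_that("single-predictor solution matches a 1-D numeric minimizer", {
  set.seed(4)
  x <- matrix(rnorm(30), dimnames = list(NULL, "g"))
  x <- (x - mean(x)) / sd(x)
  y <- 0.4 * x[, 1] + rnorm(30)
  for (al in c(0.3, 0.7, 1)) {
    for (lam in c(0.5, 3, 12)) {
      f <- fit_en(x, y, al, lam, tol = 1e-10)
      obj <- function(b) sum((y - mean(y) - x %*% b)^2) +
        lam * ((1 - al) * b^2 + al * abs(b))
      num <- optimize(obj, c(-4, 4), tol = 1e-12)$minimum
      target <- if (abs(num) < 1e-9) 0 else num
      expect_lt(abs(f$beta - target), 1e-8)
    }
  }
})

test_that("lasso path agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  X <- std_design(80, 60, seed = 5)
  set.seed(6)
  y <- drop(X[, 1:3] %*% c(1, -0.6, 0.4)) + rnorm(80)
  y <- (y - mean(y)) / sd(y)
  grid <- twaspipe:::.lambda_grid(X, y, 1, n_lambda = 40, ratio = 1e-2)
  p <- twaspipe:::.en_path(X, y, grid, 1)
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = grid / (2 * 80),
                      standardize = FALSE, thresh = 1e-14, maxit = 1e6)
  k <- ncol(g$beta)
  expect_lt(max(abs(p$beta[, seq_len(k)] - as.matrix(g$beta))), 1e-6)
})

test_that("ridge solutions equal the closed-form normal equations", {
  X <- std_design(40, 25, seed = 7)
  set.seed(8)
  y <- rnorm(40)
  f <- fit_en(X, y, alpha = 0, lambda = 7)
  Xc <- scale(X, scale = FALSE)
  bex <- solve(crossprod(Xc) + diag(7, 25), crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(f$beta - drop(bex))), 1e-10)
})

test_that("objective audit: solutions beat the zero vector and perturbations", {
  X <- std_design(50, 30, seed = 9)
  set.seed(10)
  y <- drop(X[, 1:2] %*% c(0.8, -0.5)) + rnorm(50)
  for (al in c(0.2, 0.5, 1)) {
    lam <- twaspipe:::.lambda_max(X, y, al) * 0.2
    f <- fit_en(X, y, al, lam)
    zero_obj <- en_obj_ref(X, y, mean(y), rep(0, 30), al, lam)
    expect_lte(f$objective, zero_obj + 1e-10)
    set.seed(11)
    for (i in 1:50) {
      bp <- f$beta + rnorm(30, 0, 1e-3)
      expect_lte(f$objective,
                 en_obj_ref(X, y, f$intercept, bp, al, lam) + 1e-10)
    }
  }
})

test_that("KKT conditions hold at convergence", {
  X <- std_design(60, 100, seed = 12)
  set.seed(13)
  y <- drop(X[, 1:4] %*% c(1, 0.7, -0.6, 0.5)) + rnorm(60)
  for (al in c(0.4, 1)) {
    grid <- twaspipe:::.lambda_grid(X, y, al)
    p <- twaspipe:::.en_path(X, y, grid, al)
    for (i in c(15, 50, 85)) {
      lam <- grid[i]
      b <- p$beta[, i]
      r <- y - p$intercept[i] - drop(X %*% b)
      grad <- drop(crossprod(X, r))
      nz <- b != 0
      if (any(nz))
        expect_lt(max(abs(2 * grad[nz] - 2 * lam * (1 - al) * b[nz] -
                            lam * al * sign(b[nz]))), 1e-6)
      if (any(!nz))
        expect_lte(max(abs(2 * grad[!nz])), lam * al + 1e-6)
    }
  }
})

test_that("cross-validation honours the 1SE rule and fold determinism", {
  X <- std_design(60, 40, seed = 14)
  set.seed(15)
  y <- drop(X[, 1] * 0.9) + rnorm(60)
  y <- (y - mean(y)) / sd(y)
  cv1 <- cross_validate(X, y, alpha_grid = c(0.5, 1), k = 5, seed = 7)
  cv2 <- cross_validate(X, y, alpha_grid = c(0.5, 1), k = 5, seed = 7)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$lambda_1se, cv2$lambda_1se)
  expect_identical(cv1$alpha_selected, cv2$alpha_selected)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  for (pa in cv1$per_alpha) {
    expect_true(all(pa$cv_se >= 0))
    expect_gte(pa$lambda_1se, pa$lambda_min)
    # the 1SE lambda is the LARGEST grid value within one SE of the min
    i_min <- which.min(pa$cv_mean)
    thr <- pa$cv_mean[i_min] + pa$cv_se[i_min]
    i_1se <- match(pa$lambda_1se, pa$lambda_grid)
    expect_true(pa$cv_mean[i_1se] <= thr)
    if (i_1se > 1) expect_true(all(pa$cv_mean[seq_len(i_1se - 1)] > thr))
  }
  expect_error(cross_validate(X, rep(1, 60), k = 5), "constant")
})

test_that("selected set at lambda_1se is contained in the set at lambda_min", {
  X <- std_design(80, 60, seed = 16)
  set.seed(17)
  y <- drop(X[, 1:5] %*% rep(0.5, 5)) + rnorm(80)
  y <- (y - mean(y)) / sd(y)
  cv <- cross_validate(X, y, alpha_grid = c(0.5), k = 10, seed = 1)
  pa <- cv$per_alpha[["0.5"]]
  f1 <- fit_en(X, y, 0.5, pa$lambda_1se)
  f2 <- fit_en(X, y, 0.5, pa$lambda_min)
  s1 <- names(f1$beta)[f1$beta != 0]
  s2 <- names(f2$beta)[f2$beta != 0]
  expect_true(all(s1 %in% s2))
})

test_that("null data yield empty 1SE selections in most replicates", {
  empty <- logical(10)
  for (r in 1:10) {
    X <- std_design(60, 150, seed = 300 + r)
    set.seed(400 + r)
    y <- rnorm(60)
    y <- (y - mean(y)) / sd(y)
    cv <- cross_validate(X, y, alpha_grid = c(0.5), k = 10, seed = r)
    sel <- select_candidates_1se(cv, X, y)
    empty[r] <- length(sel$genes) == 0
  }
  expect_gte(sum(empty), 9)
})

test_that("a single dominant effect is always selected", {
  for (r in 1:5) {
    X <- std_design(100, 80, seed = 500 + r)
    set.seed(600 + r)
    y <- 2 * X[, 37] + rnorm(100)
    y <- (y - mean(y)) / sd(y)
    cv <- cross_validate(X, y, alpha_grid = c(0.5), k = 10, seed = r)
    sel <- select_candidates_1se(cv, X, y)
    expect_true("g037" %in% sel$genes)
  }
})

test_that("Wald statistics follow the chi-square reference", {
  w0 <- wald_test(0, 1)
  expect_equal(w0$W, 0)
  expect_equal(w0$p, 1)
  w <- wald_test(2, 1)
  expect_equal(w$W, 4)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(w$p - 0.0455), 5e-4)
  bs <- seq(0.1, 3, by = 0.1)
  ps <- wald_test(bs, 1)$p
  expect_true(all(diff(ps) < 0))
  expect_error(wald_test(1, 0), "positive")
})

test_that("mixed model with identity kinship collapses to simple regression", {
  set.seed(18)
  x <- rnorm(70)
  y <- 0.5 * x + rnorm(70)
  f <- fit_lmm_gene(x, y, diag(70))
  ref <- summary(lm(y ~ x))$coefficients
  expect_lt(abs(f$effect - ref[2, 1]), 1e-6)
  expect_lt(abs(f$se - ref[2, 2]), 1e-6)
  expect_error(fit_lmm_gene(x, y, matrix(-1, 70, 70)), "positive semidefinite")
})

test_that("mixed-model gene test holds its size and recovers effects under polygenic structure", {
  set.seed(19)
  n <- 80
  W <- matrix(rbinom(n * 60, 2, 0.3), n, 60)
  Ws <- scale(W)
  K <- tcrossprod(Ws) / 60
  K <- K + diag(1e-8, n)
  reject <- 0
  reps <- 120
  bias <- numeric(40)
  eig <- eigen(K, symmetric = TRUE)
  for (r in seq_len(reps)) {
    set.seed(700 + r)
    u <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * rnorm(n))
    x <- rnorm(n)
    y <- drop(u) + rnorm(n)
    f <- fit_lmm_gene(x, y, K)
    if (f$p < 0.05) reject <- reject + 1
    if (r <= 40) {
      y2 <- 0.5 * x + drop(u) + rnorm(n)
      bias[r] <- fit_lmm_gene(x, y2, K)$effect - 0.5
    }
  }
  expect_lte(reject / reps, 0.09)  # nominal 0.05 with Monte-Carlo slack
  expect_lt(abs(mean(bias)), 0.05)
})
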