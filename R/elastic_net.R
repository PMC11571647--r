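#' Fit the elastic-net objective at fixed tuning values
#'
#' Coordinate descent on the raw residual-sum-of-squares objective
#' \deqn{(y - \mu 1 - Xb)'(y - \mu 1 - Xb) +
#'       \lambda \sum_i [(1-\alpha) b_i^2 + \alpha |b_i|]}
#' with no 1/n or 1/2 rescaling, so the single-coordinate update is
#' \eqn{b_j = S(x_j'r, \lambda\alpha/2) / (x_j'x_j + \lambda(1-\alpha))}.
#' `alpha = 1` is the LASSO, `alpha = 0` ridge regression. Inputs are
#' expected standardized (see [standardize_rows()]); the intercept is
#' estimated regardless. Convergence is declared when the largest
#' coefficient change in a full sweep drops below `tol`.
#'
#' @param X n x m predictor matrix (samples x genes), standardized columns.
#' @param y Length-n response, standardized.
#' @param alpha Penalty mixture in `[0, 1]`.
#' @param lambda Non-negative penalty strength (raw-RSS scale).
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_sweeps Sweep budget.
#' @return List of class `"en_fit"`: `intercept`, `beta` (named), `alpha`,
#'   `lambda`, `objective`, `sweeps`.
#' @export
fit_en <- function(X, y, alpha, lambda, tol = 1e-7, max_sweeps = 10000L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (lambda < 0) stop("lambda must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  sol <- .en_path(X, y, as.numeric(lambda), alpha, tol, max_sweeps)
  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  fit <- list(intercept = sol$intercept[1L], beta = beta, alpha = alpha,
              lambda = lambda, sweeps = sol$sweeps[1L])
  fit$objective <- en_objective(X, y, fit)
  class(fit) <- "en_fit"
  fit
}

#' Value of the elastic-net objective for a fit
#'
#' @param X,y Data as in [fit_en()].
#' @param fit An `"en_fit"` (or any list with `intercept`, `beta`, `alpha`,
#'   `lambda`).
#' @return The objective value (RSS plus penalty).
#' @export
en_objective <- function(X, y, fit) {
  r <- y - fit$intercept - drop(X %*% fit$beta)
  sum(r^2) + fit$lambda * sum((1 - fit$alpha) * fit$beta^2 +
                                fit$alpha * abs(fit$beta))
}

# Smallest lambda at which all coefficients are zero. All-zero requires
# |x_j'(y - ybar)| <= lambda*alpha/2 for every j. For small alpha the grid
# anchor uses alpha floored at 1e-3 (ridge never fully shrinks).
.lambda_max <- function(X, y, alpha) {
  yc <- y - mean(y)
  2 * max(abs(crossprod(X, yc))) / max(alpha, 1e-3)
}

.lambda_grid <- function(X, y, alpha, n_lambda = 100L, ratio = 1e-3) {
  lmax <- .lambda_max(X, y, alpha)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# Full descending-lambda path at one alpha. alpha > 0 runs the compiled
# coordinate-descent/active-set solver; alpha = 0 (pure ridge) has the
# closed-form minimizer b = (Xc'Xc + lambda I)^{-1} Xc'yc, evaluated for
# every lambda at once through one SVD of the centered predictor matrix —
# the identical objective, solved exactly.
.en_path <- function(X, y, lambdas, alpha, tol = 1e-7, max_sweeps = 10000L) {
  if (alpha == 0) {
    sol <- .ridge_path(X, y, lambdas)
  } else {
    sol <- en_path_cpp(X, y, lambdas, alpha, tol, as.integer(max_sweeps))
  }
  rownames(sol$beta) <- colnames(X)
  sol$lambdas <- lambdas
  sol
}

.ridge_path <- function(X, y, lambdas) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  ybar <- mean(y)
  sv <- svd(Xc)
  uty <- drop(crossprod(sv$u, y - ybar))
  beta <- vapply(lambdas, function(l) {
    ratio <- ifelse(sv$d > 1e-10, sv$d / (sv$d^2 + l), 0)
    drop(sv$v %*% (ratio * uty))
  }, numeric(ncol(X)))
  beta <- matrix(beta, nrow = ncol(X))
  list(beta = beta, intercept = ybar - drop(crossprod(xbar, beta)),
       sweeps = integer(length(lambdas)))
}

#' K-fold cross-validation over an alpha grid with the 1SE rule
#'
#' For each `alpha`, a 100-value log-spaced lambda grid is generated from
#' the all-zero threshold \eqn{\lambda_{max}} down to `ratio` times it, and
#' the full warm-started path is fit on each training fold. Folds come from
#' one seeded permutation shared across alphas. Per (alpha, lambda), the CV
#' error is the mean of per-fold validation MSEs and its SE the SD of fold
#' errors over \eqn{\sqrt k}. `lambda_min` minimizes the CV error within an
#' alpha; `lambda_1se` is the largest lambda whose CV error is within one SE
#' (at `lambda_min`) of that minimum — ties resolve to the largest, i.e.
#' most regularized, lambda. `alpha_selected` attains the global CV minimum.
#'
#' @param X,y Standardized data as in [fit_en()].
#' @param alpha_grid Alphas to scan (default `seq(0.1, 0.9, 0.1)`).
#' @param k Folds (default 10, minimum 3).
#' @param seed Seed for the fold permutation.
#' @param n_lambda,ratio Lambda grid size and ratio of smallest to largest.
#' @param tol,max_sweeps Solver controls.
#' @return List of class `"cv_path"`: `per_alpha` (per-alpha list with
#'   `lambda_grid`, `cv_mean`, `cv_se`, `lambda_min`, `lambda_1se`),
#'   `alpha_selected`, `lambda_min`, `lambda_1se`, `fold_id`, `fold_count`,
#'   `fold_seed`.
#' @export
cross_validate <- function(X, y, alpha_grid = seq(0.1, 0.9, by = 0.1),
                           k = 10L, seed = 1L, n_lambda = 100L, ratio = 1e-3,
                           tol = 1e-7, max_sweeps = 10000L) {
  n <- length(y)
  if (k < 3L) stop("k must be at least 3")
  if (n < 2L * k) stop("need n >= 2k samples")
  if (sd(y) == 0) stop("constant response")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(k), n))
  per_alpha <- list()
  for (a in alpha_grid) {
    grid <- .lambda_grid(X, y, a, n_lambda, ratio)
    fold_err <- matrix(NA_real_, nrow = k, ncol = n_lambda)
    for (f in seq_len(k)) {
      tr <- fold_id != f
      sol <- .en_path(X[tr, , drop = FALSE], y[tr], grid, a, tol, max_sweeps)
      pred <- X[!tr, , drop = FALSE] %*% sol$beta +
        rep(sol$intercept, each = sum(!tr))
      fold_err[f, ] <- colMeans((y[!tr] - pred)^2)
    }
    cv_mean <- colMeans(fold_err)
    cv_se <- apply(fold_err, 2L, sd) / sqrt(k)
    i_min <- which.min(cv_mean)
    ok <- cv_mean <= cv_mean[i_min] + cv_se[i_min]
    i_1se <- min(which(ok))  # grid is descending: smallest index = largest lambda
    per_alpha[[as.character(a)]] <- list(
      alpha = a, lambda_grid = grid, cv_mean = cv_mean, cv_se = cv_se,
      fold_err = fold_err,
      lambda_min = grid[i_min], lambda_1se = grid[i_1se],
      cv_min = cv_mean[i_min])
  }
  mins <- vapply(per_alpha, `[[`, numeric(1), "cv_min")
  best <- per_alpha[[which.min(mins)]]
  structure(list(per_alpha = per_alpha, alpha_grid = alpha_grid,
                 alpha_selected = best$alpha,
                 lambda_min = best$lambda_min, lambda_1se = best$lambda_1se,
                 fold_id = fold_id, fold_count = k, fold_seed = seed),
            class = "cv_path")
}

#' Select candidate genes by the elastic-net 1SE rule
#'
#' Refits on all data at (`alpha_selected`, `lambda_1se`) and returns the
#' genes with exactly non-zero coefficients — coordinate descent produces
#' exact zeros, so no threshold is involved. This is the selection rule that
#' needs no significance test.
#'
#' @param cv A [cross_validate()] result.
#' @param X,y The full standardized data.
#' @param ... Passed to [fit_en()].
#' @return List with `genes` (character vector), `fit` (the `"en_fit"`).
#' @export
select_candidates_1se <- function(cv, X, y, ...) {
  stopifnot(inherits(cv, "cv_path"))
  fit <- fit_en(X, y, cv$alpha_selected, cv$lambda_1se, ...)
  list(genes = names(fit$beta)[fit$beta != 0], fit = fit)
}

#' Wald test for estimated effects
#'
#' \eqn{W = b^2 / var(b)}, referred to the upper tail of a chi-square
#' distribution with one degree of freedom.
#'
#' @param b Effect estimate(s).
#' @param var_b Positive variance estimate(s), recycled against `b`.
#' @return data.frame with columns `b`, `var_b`, `W`, `p`.
#' @export
wald_test <- function(b, var_b) {
  if (any(var_b <= 0)) stop("var_b must be positive")
  W <- b^2 / var_b
  data.frame(b = b, var_b = var_b, W = W,
             p = pchisq(W, df = 1, lower.tail = FALSE))
}

#' Sandwich variance of penalized coefficients on the active set
#'
#' For the non-zero coefficients A of an elastic-net fit, the variance is
#' estimated as \eqn{\sigma^2 H^{-1} X_A'X_A H^{-1}} with
#' \eqn{H = X_A'X_A + \lambda(1-\alpha) I} and \eqn{\sigma^2} the residual
#' variance on the active-set degrees of freedom. This is an openly stated
#' approximation: penalized estimators have no exact finite-sample Wald
#' variance, and the resulting test is a screening device, not an exact
#' inference.
#'
#' @param X,y Data used for the fit.
#' @param fit An `"en_fit"`.
#' @return Named variance vector over the active set (length 0 if empty).
#' @export
en_coef_variance <- function(X, y, fit) {
  act <- which(fit$beta != 0)
  if (!length(act)) return(setNames(numeric(0), character(0)))
  Xa <- X[, act, drop = FALSE]
  r <- y - fit$intercept - drop(Xa %*% fit$beta[act])
  df <- max(length(y) - length(act) - 1L, 1L)
  s2 <- sum(r^2) / df
  XtX <- crossprod(Xa)
  H <- XtX + diag(fit$lambda * (1 - fit$alpha), length(act))
  Hi <- solve(H)
  v <- s2 * diag(Hi %*% XtX %*% Hi)
  setNames(pmax(v, .Machine$double.eps), names(fit$beta)[act])
}

#' Per-gene association by a penalized multi-locus model
#'
#' End-to-end association of one trait with all genes: standardize, run
#' [cross_validate()], refit at both the CV-minimum and the 1SE lambda, and
#' attach Wald statistics (active-set sandwich variance) for the non-zero
#' effects of the minimum-rule fit.
#'
#' @param expr Gene x sample normalized (log-scale) expression matrix.
#' @param trait Named or aligned numeric phenotype vector (one per sample).
#' @param alpha_grid,k,seed,... Passed to [cross_validate()].
#' @return List of class `"en_assoc"`: `cv`, `fit_1se`, `fit_min`,
#'   `selected_1se`, `selected_min` (non-zero AND Wald p < 0.05), `wald`
#'   (data.frame for the min-rule active set), `n`.
#' @export
en_assoc <- function(expr, trait, alpha_grid = seq(0.1, 0.9, by = 0.1),
                     k = 10L, seed = 1L, ...) {
  stopifnot(is.matrix(expr), ncol(expr) == length(trait))
  keep <- !is.na(trait)
  expr <- expr[, keep, drop = FALSE]
  trait <- trait[keep]
  Xg <- standardize_rows(expr)
  X <- t(Xg)
  y <- standardize_vector(trait)
  cv <- cross_validate(X, y, alpha_grid = alpha_grid, k = k, seed = seed, ...)
  sel <- select_candidates_1se(cv, X, y)
  a <- cv$per_alpha[[as.character(cv$alpha_selected)]]
  fit_min <- fit_en(X, y, cv$alpha_selected, a$lambda_min)
  vb <- en_coef_variance(X, y, fit_min)
  wald <- if (length(vb)) wald_test(fit_min$beta[names(vb)], vb) else
    data.frame(b = numeric(0), var_b = numeric(0), W = numeric(0), p = numeric(0))
  structure(list(cv = cv, fit_1se = sel$fit, fit_min = fit_min,
                 selected_1se = sel$genes,
                 selected_min = rownames(wald)[wald$p < 0.05],
                 wald = wald, n = length(y)),
            class = "en_assoc")
}
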