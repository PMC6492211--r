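#' L1-penalized logistic regression path
#'
#' Fits the lasso-penalized logistic likelihood
#' `-(1/n) sum_i w_i [y_i eta_i - log(1 + exp(eta_i))] + lambda ||beta||_1`
#' along a decreasing penalty grid, with an unpenalized intercept and
#' internally standardized covariates (coefficients returned on the original
#' scale). The convex solver is glmnet's coordinate descent with warm starts,
#' run at a tight tolerance so the Karush-Kuhn-Tucker conditions hold at
#' every grid point. Observation weights are normalized internally so the
#' solution is invariant to rescaling them.
#'
#' @param X covariate matrix (no intercept column).
#' @param y binary 0/1 outcome.
#' @param weights nonnegative per-row weights (default all equal).
#' @param lambda optional user grid (decreasing); if `NULL`, 100 log-spaced
#'   values from the data-derived `lambda_max` (smallest penalty with all
#'   slopes zero) down to `0.001 * lambda_max`.
#' @param nlambda,lambda_min_ratio grid size and lower end (as a fraction of
#'   `lambda_max`) for the automatic grid.
#' @return a `penalty_path`: `lambda`, `a0` (intercepts), `beta`
#'   (p x nlambda sparse slope matrix), and the underlying fit.
#' @export
fit_path <- function(X, y, weights = NULL, lambda = NULL, nlambda = 100,
                     lambda_min_ratio = 0.001) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (any(weights < 0)) stop("weights must be nonnegative")
  args <- list(x = X, y = y, family = "binomial", weights = weights,
               standardize = TRUE, thresh = 1e-10, maxit = 1e6)
  if (is.null(lambda)) {
    args$nlambda <- nlambda
    args$lambda.min.ratio <- lambda_min_ratio
  } else {
    args$lambda <- lambda
  }
  g <- do.call(glmnet::glmnet, args)
  structure(list(lambda = g$lambda, a0 = as.numeric(g$a0), beta = g$beta,
                 fit = g, weights = weights),
            class = "penalty_path")
}

#' Coefficients of a penalty path at a given penalty
#' @param path a [fit_path()] object.
#' @param s penalty value (one of the grid values, or interpolated).
#' @return numeric vector `c(intercept, slopes)`.
#' @export
path_coef <- function(path, s) {
  as.numeric(glmnet::coef.glmnet(path$fit, s = s, exact = FALSE))
}

#' Stratified, optionally subject-grouped, fold assignment
#'
#' Folds are assigned at the unit level — rows when `group_ids` is `NULL`,
#' otherwise whole subjects, so that in stacked multiply-imputed data a
#' subject's m rows are either all held out or all retained. Units are
#' stratified by outcome to avoid single-class folds at small n.
#'
#' @param y per-row binary outcome.
#' @param k number of folds.
#' @param group_ids optional per-row subject identifier.
#' @param seed optional integer seed.
#' @return integer per-row fold id in `1..k`.
#' @export
assign_folds <- function(y, k = 10, group_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group_ids)) group_ids <- seq_along(y)
  units <- !duplicated(group_ids)
  uid <- group_ids[units]
  uy <- y[units]
  fold_of_unit <- integer(length(uid))
  for (cls in unique(uy)) {
    idx <- which(uy == cls)
    fold_of_unit[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold_of_unit[match(group_ids, uid)]
}

#' Cross-validated deviance along the penalty grid
#'
#' K-fold cross-validation of [fit_path()]: each fold's model is fit on the
#' remaining folds (same penalty grid, warm starts) and scored on the
#' held-out rows by the weighted binomial deviance
#' `-2 * sum(w * (y log p + (1-y) log(1-p))) / sum(w)` with predicted
#' probabilities clipped at 1e-15. The curve reports the across-fold mean
#' and its standard error `sd(folds)/sqrt(k)` per penalty.
#'
#' @inheritParams fit_path
#' @param k number of folds (default 10).
#' @param group_ids optional per-row subject id for grouped assignment.
#' @param seed seed for the fold assignment.
#' @return a `cv_curve`: `lambda`, `cvm`, `cvse`, `fold_dev` (k x nlambda),
#'   `foldid`, `path` (full-data path on the same grid).
#' @export
cv_curve <- function(X, y, weights = NULL, k = 10, group_ids = NULL,
                     seed = NULL, lambda = NULL) {
  stopifnot(k >= 2)
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  path <- fit_path(X, y, weights, lambda = lambda)
  grid <- path$lambda
  foldid <- assign_folds(y, k = k, group_ids = group_ids, seed = seed)
  fold_dev <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- foldid != f
    gtr <- fit_path(X[tr, , drop = FALSE], y[tr], weights[tr], lambda = grid)
    ph <- predict(gtr$fit, X[!tr, , drop = FALSE], type = "response")
    wte <- weights[!tr]
    yte <- y[!tr]
    fold_dev[f, ] <- vapply(seq_along(grid), function(l) {
      binomial_deviance(yte, ph[, l], wte)
    }, numeric(1))
  }
  structure(list(lambda = grid,
                 cvm = colMeans(fold_dev),
                 cvse = apply(fold_dev, 2, sd) / sqrt(k),
                 fold_dev = fold_dev, foldid = foldid, path = path),
            class = "cv_curve")
}

#' Choose the penalty from a cross-validation curve
#'
#' `lambda_opt` minimizes the mean cross-validated deviance (ties broken
#' toward the larger, more parsimonious penalty). `lambda_1se` is the
#' largest penalty whose mean deviance stays within one standard error —
#' the standard error at the minimizer — of the minimum.
#'
#' @param curve a [cv_curve()].
#' @return a `penalty_choice` with `lambda_opt`, `lambda_1se`, and their
#'   grid indices `i_opt`, `i_1se`.
#' @export
choose_penalty <- function(curve) {
  stopifnot(length(curve$lambda) >= 1)
  # grid is decreasing, so the first index attaining the minimum is the
  # largest (most parsimonious) minimizing penalty
  i_opt <- which.min(curve$cvm)
  thr <- curve$cvm[i_opt] + curve$cvse[i_opt]
  i_1se <- which(curve$cvm <= thr)[1]
  structure(list(lambda_opt = curve$lambda[i_opt],
                 lambda_1se = curve$lambda[i_1se],
                 i_opt = i_opt, i_1se = i_1se),
            class = "penalty_choice")
}

#' Cross-validated lasso fit with both penalty rules
#'
#' Convenience wrapper running [cv_curve()] and [choose_penalty()] once and
#' returning the coefficient vectors at the optimal and the 1-se penalty.
#'
#' @inheritParams cv_curve
#' @return list with `curve`, `choice`, `coef_opt`, `coef_1se` (each
#'   `c(intercept, slopes)` on the original covariate scale).
#' @export
lasso_cv <- function(X, y, weights = NULL, k = 10, group_ids = NULL,
                     seed = NULL) {
  curve <- cv_curve(X, y, weights, k = k, group_ids = group_ids, seed = seed)
  ch <- choose_penalty(curve)
  list(curve = curve, choice = ch,
       coef_opt = path_coef(curve$path, ch$lambda_opt),
       coef_1se = path_coef(curve$path, ch$lambda_1se))
}

#' Subgradient (KKT) residuals of a lasso solution
#'
#' For the weighted, internally standardized lasso logistic objective the
#' stationarity conditions are `score_j = lambda * sign(beta_j)` for active
#' covariates and `|score_j| <= lambda` for inactive ones, where `score_j`
#' is the weighted average score of the standardized covariate. Returns, per
#' grid point, the largest violation of these conditions; used as an
#' independent check that the solver converged.
#'
#' @param path a [fit_path()] object.
#' @param X,y,weights the data the path was fit on.
#' @return numeric vector of maximal KKT violations, one per grid lambda.
#' @export
kkt_violation <- function(path, X, y, weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  wn <- weights / sum(weights)           # weights normalized to mean 1/n
  mx <- colSums(X * wn)
  sdx <- sqrt(colSums(sweep(X, 2, mx)^2 * wn))
  Xs <- sweep(sweep(X, 2, mx), 2, sdx, "/")
  vapply(seq_along(path$lambda), function(l) {
    lam <- path$lambda[l]
    b <- as.numeric(path$beta[, l])
    eta <- path$a0[l] + drop(X %*% b)
    r <- wn * (y - plogis(eta))
    score <- drop(crossprod(Xs, r))      # gradient wrt standardized coefs
    bs <- b * sdx                        # standardized-scale coefficients
    active <- bs != 0
    v_active <- if (any(active))
      max(abs(score[active] - lam * sign(bs[active]))) else 0
    v_inactive <- if (any(!active))
      max(pmax(abs(score[!active]) - lam, 0)) else 0
    v_int <- abs(sum(r))                 # unpenalized intercept score
    max(v_active, v_inactive, v_int)
  }, numeric(1))
}
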