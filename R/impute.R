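#' Multiple imputation by chained equations
#'
#' Fills the missing covariate entries of an incomplete dataset `m` times by
#' chained equations. Missing entries are initialized by random draws from
#' the observed values of their column; then, for a fixed number of cycles,
#' each incomplete variable (visited in order of increasing missingness) is
#' regressed on all other covariates plus the outcome using the currently
#' completed data, and its missing entries are redrawn — by predictive mean
#' matching ([pmm_draw()]) for continuous variables and by
#' posterior-perturbed logistic draws ([logistic_draw()]) for binary
#' variables. The outcome is a predictor in every imputation model and is
#' never imputed (it is always fully observed here). Columns whose observed
#' values all lie in {0, 1} are treated as binary.
#'
#' @param data an `incomplete_data` (see [impose_mar()] or [read_dataset()]).
#' @param m number of completed copies (>= 2 for genuine multiple imputation).
#' @param cycles chained-equation sweeps per copy (default 5).
#' @param donors PMM donor-pool size (default 5).
#' @param seed optional integer master seed; copy `k` uses a child seed so
#'   completions are independent but jointly reproducible.
#' @return an `imputation_set`: list with `completed` (list of `m`
#'   `complete_data`), `m`, and `source` (the input).
#' @export
impute_chained <- function(data, m = 10, cycles = 5, donors = 5, seed = NULL) {
  stopifnot(inherits(data, "incomplete_data"), m >= 1)
  X0 <- data$X
  n <- nrow(X0); p <- ncol(X0)
  miss_cols <- which(colSums(is.na(X0)) > 0)
  n_miss <- colSums(is.na(X0))[miss_cols]
  if (any(n_miss == n))
    stop("unimputable: a variable has no observed values")
  visit <- miss_cols[order(n_miss)]
  is_bin <- vapply(seq_len(p), function(j) {
    v <- X0[!is.na(X0[, j]), j]
    all(v %in% c(0, 1))
  }, logical(1))
  completed <- vector("list", m)
  n_notes <- 0L
  for (k in seq_len(m)) {
    if (!is.null(seed)) set.seed(child_seed(seed, "imp", k))
    Xc <- X0
    for (j in visit) {
      mis <- is.na(X0[, j])
      Xc[mis, j] <- sample(X0[!mis, j], sum(mis), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (j in visit) {
        mis <- is.na(X0[, j])
        D <- cbind(1, Xc[, -j, drop = FALSE], data$y)
        # sub-model fallback notes are tallied and reported once per call
        withCallingHandlers({
          if (is_bin[j]) {
            Xc[, j] <- logistic_draw(Xc[, j], D, mis)
          } else {
            Xc[, j] <- pmm_draw(Xc[, j], D, mis, donors = donors)
          }
        }, message = function(cnd) {
          n_notes <<- n_notes + 1L
          invokeRestart("muffleMessage")
        })
      }
    }
    colnames(Xc) <- colnames(X0)
    completed[[k]] <- structure(list(X = Xc, y = data$y,
                                     mechanism = data$mechanism),
                                class = "complete_data")
  }
  if (n_notes > 0)
    message(sprintf(
      "impute_chained: degenerate sub-model handled (ridge fallback or constant class) in %d of %d fits",
      n_notes, m * cycles * length(visit)))
  structure(list(completed = completed, m = m, source = data),
            class = "imputation_set")
}

#' @exportS3Method base::print
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: m = %d completions of n = %d, p = %d\n",
              x$m, length(x$source$y), ncol(x$source$X)))
  invisible(x)
}

#' Predictive mean matching draw for one continuous variable
#'
#' Fits a linear regression of the observed target values on the design,
#' perturbs the coefficients with a draw from their approximate posterior
#' (sigma^2 from the scaled inverse chi-square, beta from
#' N(beta_hat, sigma^2 (X'X)^-1)), predicts means for observed cases from
#' `beta_hat` and for missing cases from the perturbed draw, and replaces
#' each missing entry by the observed value of one of the `donors` cases
#' with closest predicted mean, chosen uniformly at random. Every imputed
#' value is therefore an observed donor value.
#'
#' @param target numeric column (current completed values; only entries with
#'   `mis == FALSE` are treated as observed data).
#' @param design matrix of predictors including an intercept column.
#' @param mis logical vector marking the entries to impute.
#' @param donors donor-pool size.
#' @return the column with `mis` entries replaced by donor values.
#' @export
pmm_draw <- function(target, design, mis, donors = 5) {
  obs <- !mis
  if (sum(obs) < donors) stop("fewer observed cases than donors")
  if (!any(mis)) return(target)
  Xo <- design[obs, , drop = FALSE]
  yo <- target[obs]
  qrX <- qr(Xo)
  rank_def <- qrX$rank < ncol(Xo)
  if (rank_def) {
    # singular design: ridge-stabilized normal equations
    A <- crossprod(Xo) + diag(1e-6, ncol(Xo))
    bhat <- drop(solve(A, crossprod(Xo, yo)))
    U <- chol(solve(A))
  } else {
    bhat <- qr.coef(qrX, yo)
    R <- qr.R(qrX)
    U <- backsolve(R, diag(ncol(Xo)))   # (X'X)^{-1} = U U'
  }
  res <- yo - drop(Xo %*% bhat)
  df <- max(sum(obs) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  bstar <- bhat + drop(U %*% rnorm(ncol(Xo))) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% bhat)
  yhat_mis <- drop(design[mis, , drop = FALSE] %*% bstar)
  out <- target
  idx_mis <- which(mis)
  for (i in seq_along(idx_mis)) {
    d <- abs(yhat_obs - yhat_mis[i])
    pool <- order(d)[seq_len(donors)]
    out[idx_mis[i]] <- yo[sample(pool, 1)]
  }
  out
}

#' Posterior-perturbed logistic draw for one binary variable
#'
#' Fits a logistic regression of the observed target on the design, draws
#' coefficients from the normal approximation to their posterior
#' N(beta_hat, Cov_hat), and imputes missing entries as Bernoulli draws from
#' the resulting predicted probabilities. If only one class is observed the
#' constant class is imputed (with a message); if the fit separates, a
#' ridge-stabilized fit is used instead (with a message).
#'
#' @inheritParams pmm_draw
#' @return the column with `mis` entries replaced by 0/1 draws.
#' @export
logistic_draw <- function(target, design, mis) {
  obs <- !mis
  if (!any(mis)) return(target)
  yo <- target[obs]
  out <- target
  if (length(unique(yo)) < 2) {
    message("logistic_draw: one-class observed target; imputing the constant class")
    out[mis] <- yo[1]
    return(out)
  }
  Xo <- design[obs, , drop = FALSE]
  fit <- irls_logit(Xo, yo)
  if (!fit$converged || fit$separated) {
    message("logistic_draw: separation detected; using ridge-stabilized fit")
    fit <- irls_logit(Xo, yo, ridge = 0.1)
  }
  U <- tryCatch(chol(fit$cov), error = function(e) {
    chol(fit$cov + diag(1e-10, ncol(fit$cov)))
  })
  bstar <- fit$coef + drop(t(U) %*% rnorm(length(fit$coef)))
  pm <- plogis(drop(design[mis, , drop = FALSE] %*% bstar))
  out[mis] <- rbinom(sum(mis), 1L, pm)
  out
}

#' Write an imputation set to disk
#'
#' Writes `imp_001.csv ... imp_<m>.csv` plus `manifest.json` into `dir`.
#' @param imps an `imputation_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputations <- function(imps, dir) {
  stopifnot(inherits(imps, "imputation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("imp_%03d.csv", seq_len(imps$m))
  for (k in seq_len(imps$m))
    write_dataset(imps$completed[[k]], file.path(dir, files[k]))
  jsonlite::write_json(list(m = imps$m, files = files),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
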