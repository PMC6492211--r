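#' Pooled prediction models
#'
#' A `pooled_model` is the final product of every selection strategy: a
#' single intercept and p-vector of slopes (zero outside the selected set),
#' tagged with the method name, the penalty rule (`"optimal"`, `"1se"` or
#' `"none"`) and the recalibration applied (`"none"`, `"score"`, `"refit"`).
#' Predictions depend only on these coefficients — pooling happens before
#' prediction, never by averaging per-imputation prediction sets.
#'
#' @param intercept scalar intercept.
#' @param slopes length-p slope vector.
#' @param selected integer index set of selected covariates; slopes outside
#'   it are forced to zero.
#' @param method method tag (`FULL`, `TrueC`, `BBeF`, `BLaF`, `SepAv`,
#'   `SepAvF`, `Stack`, `StackW`).
#' @param penalty_rule,recalibration provenance tags.
#' @param info free-form list (inclusion frequencies, gamma, ...).
#' @return a `pooled_model`.
#' @export
pooled_model <- function(intercept, slopes, selected, method,
                         penalty_rule = "none", recalibration = "none",
                         info = list()) {
  methods <- c("FULL", "TrueC", "BBeF", "BLaF", "SepAv", "SepAvF",
               "Stack", "StackW")
  if (!method %in% methods) stop("unknown method tag: ", method)
  slopes_out <- numeric(length(slopes))
  slopes_out[selected] <- slopes[selected]
  structure(list(intercept = intercept, slopes = slopes_out,
                 selected = sort(as.integer(selected)), method = method,
                 penalty_rule = penalty_rule, recalibration = recalibration,
                 info = info),
            class = "pooled_model")
}

#' @exportS3Method base::print
print.pooled_model <- function(x, ...) {
  cat(sprintf("pooled_model %s (penalty %s, recalibration %s): %d selected\n",
              x$method, x$penalty_rule, x$recalibration, length(x$selected)))
  invisible(x)
}

#' @param object a `pooled_model`.
#' @param newdata covariate matrix or `complete_data`.
#' @param ... unused.
#' @rdname pooled_model
#' @export
predict.pooled_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "complete_data")) newdata$X else as.matrix(newdata)
  plogis(object$intercept + drop(X %*% object$slopes))
}

#' Backward elimination by AIC
#'
#' Greedy backward elimination for a logistic model: starting from all
#' covariates, repeatedly remove the single covariate whose removal most
#' decreases the AIC; stop when no removal decreases it. The intercept is
#' always retained. Complete or quasi-complete separation at any step is a
#' convergence failure (condition class `mivarsel_convergence_error`);
#' callers in the bootstrap loop catch it, exclude the fit and count it.
#'
#' @param X covariate matrix.
#' @param y binary outcome.
#' @return sorted integer vector of retained covariate indices (possibly
#'   empty).
#' @export
backward_eliminate_aic <- function(X, y) {
  X <- as.matrix(X)
  active <- seq_len(ncol(X))
  fit <- irls_logit(cbind(1, X), y)
  if (!fit$converged || fit$separated)
    stop(condition_convergence_error("separation in full model", 0L))
  aic <- fit$aic
  coef_cur <- fit$coef
  step <- 0L
  repeat {
    if (length(active) == 0) break
    step <- step + 1L
    cand_aic <- rep(Inf, length(active))
    cand_coef <- vector("list", length(active))
    for (ii in seq_along(active)) {
      keep <- active[-ii]
      # warm start from the current model with the dropped column removed
      f <- irls_logit(cbind(1, X[, keep, drop = FALSE]), y,
                      start = coef_cur[-(ii + 1)])
      if (!f$converged || f$separated)
        stop(condition_convergence_error("separation during elimination", step))
      cand_aic[ii] <- f$aic
      cand_coef[[ii]] <- f$coef
    }
    best <- which.min(cand_aic)
    if (cand_aic[best] >= aic) break
    aic <- cand_aic[best]
    coef_cur <- cand_coef[[best]]
    active <- active[-best]
  }
  sort(active)
}

base_selector <- function(base, X, y, seed = NULL, k = 10) {
  if (base == "aic_backward") return(backward_eliminate_aic(X, y))
  cv <- lasso_cv(X, y, k = k, seed = seed)
  co <- if (base == "lasso_1se") cv$coef_1se else cv$coef_opt
  which(co[-1] != 0)
}

#' Bootstrap variable inclusion frequencies over imputed datasets
#'
#' From each of the m completed datasets, draws B bootstrap resamples
#' (subjects with replacement, original size) and runs the base selector on
#' each; the inclusion frequency of a covariate is the fraction of the m*B
#' fits that retained it. For the lasso bases the penalty is re-chosen by
#' cross-validation within every bootstrap sample. Base-selector convergence
#' failures are logged and removed from the denominator.
#'
#' @param imps an [impute_chained()] result.
#' @param B bootstrap resamples per completion.
#' @param base `"lasso_1se"`, `"lasso_opt"` or `"aic_backward"`.
#' @param seed optional master seed.
#' @param k CV folds for the lasso bases.
#' @return an `inclusion_freq`: `freq` (length p), `fits` (logical matrix,
#'   one row per successful fit), `failures`, `B`, `m`, `base`.
#' @export
bootstrap_inclusion <- function(imps, B, base = c("lasso_1se", "lasso_opt",
                                                  "aic_backward"),
                                seed = NULL, k = 10) {
  base <- match.arg(base)
  stopifnot(inherits(imps, "imputation_set"), B >= 1)
  n <- length(imps$source$y)
  p <- ncol(imps$source$X)
  fits <- matrix(FALSE, 0, p)
  failures <- 0L
  for (kk in seq_len(imps$m)) {
    dat <- imps$completed[[kk]]
    for (b in seq_len(B)) {
      if (!is.null(seed)) set.seed(child_seed(seed, "boot", kk, b))
      idx <- sample.int(n, n, replace = TRUE)
      sel <- tryCatch(
        base_selector(base, dat$X[idx, , drop = FALSE], dat$y[idx],
                      seed = if (is.null(seed)) NULL
                             else child_seed(seed, "bootcv", kk, b), k = k),
        mivarsel_convergence_error = function(e) NULL)
      if (is.null(sel)) { failures <- failures + 1L; next }
      row <- rep(FALSE, p); row[sel] <- TRUE
      fits <- rbind(fits, row)
    }
  }
  if (nrow(fits) == 0)
    stop(condition_convergence_error("all bootstrap fits failed"))
  structure(list(freq = colMeans(fits), fits = fits, failures = failures,
                 B = B, m = imps$m, base = base),
            class = "inclusion_freq")
}

pooled_refit <- function(imps, selected) {
  p <- ncol(imps$source$X)
  coefs <- matrix(0, imps$m, p + 1)
  for (kk in seq_len(imps$m)) {
    dat <- imps$completed[[kk]]
    f <- irls_logit(cbind(1, dat$X[, selected, drop = FALSE]), dat$y)
    if (!f$converged || f$separated)
      stop(condition_convergence_error("separation in pooled refit"))
    coefs[kk, c(1, 1 + selected)] <- f$coef
  }
  colMeans(coefs)
}

#' Final model from inclusion frequencies
#'
#' Selects the covariates whose inclusion frequency is at least `threshold`
#' (inclusive: a frequency of exactly 50% is selected), refits the selected
#' set by unpenalized logistic regression on each completed dataset, and
#' averages the coefficient estimates (Rubin point-estimate pooling). An
#' empty selection yields an intercept-only model (with a message).
#'
#' @param freqs a [bootstrap_inclusion()] result.
#' @param imps the `imputation_set` the frequencies were computed on.
#' @param threshold inclusion-frequency cutoff (default 0.5).
#' @param method method tag for the result (`"BBeF"` or `"BLaF"`).
#' @return a [pooled_model()].
#' @export
select_by_frequency <- function(freqs, imps, threshold = 0.5,
                                method = c("BLaF", "BBeF")) {
  method <- match.arg(method)
  stopifnot(inherits(freqs, "inclusion_freq"))
  selected <- which(freqs$freq >= threshold)
  p <- ncol(imps$source$X)
  if (length(selected) == 0) {
    message("select_by_frequency: empty selection; intercept-only model")
    ints <- vapply(imps$completed, function(d)
      irls_logit(matrix(1, length(d$y), 1), d$y)$coef, numeric(1))
    co <- c(mean(ints), numeric(p))
  } else {
    co <- pooled_refit(imps, selected)
  }
  rule <- if (freqs$base == "lasso_opt") "optimal"
          else if (freqs$base == "lasso_1se") "1se" else "none"
  pooled_model(co[1], co[-1], selected, method, penalty_rule = rule,
               info = list(freq = freqs$freq, threshold = threshold,
                           failures = freqs$failures))
}

#' Lasso on each imputed dataset separately, averaged
#'
#' Runs a cross-validated lasso on each completed dataset with its own fold
#' assignment, extracts the coefficients at the chosen penalty, and pools by
#' averaging all m coefficient vectors (a completion where a variable was
#' not selected contributes a zero). The selected set is the union of the
#' per-completion active sets (`SepAv`) or the variables active in at least
#' half of the completions (`SepAvF`, `require_majority = TRUE`).
#'
#' @param imps an `imputation_set`.
#' @param penalty_rule `"1se"` or `"optimal"`.
#' @param require_majority `FALSE` for SepAv (union), `TRUE` for SepAvF
#'   (inclusion frequency >= 50% over completions).
#' @param seed optional master seed for the fold assignments.
#' @param k CV folds.
#' @return a [pooled_model()].
#' @export
select_sepav <- function(imps, penalty_rule = c("1se", "optimal"),
                         require_majority = FALSE, seed = NULL, k = 10) {
  penalty_rule <- match.arg(penalty_rule)
  cvs <- sepav_cvs(imps, seed = seed, k = k)
  sepav_pool(cvs, penalty_rule, require_majority, imps)
}

# per-completion CV fits, shared between the 1-se and optimal variants
sepav_cvs <- function(imps, seed = NULL, k = 10) {
  lapply(seq_len(imps$m), function(kk) {
    dat <- imps$completed[[kk]]
    lasso_cv(dat$X, dat$y, k = k,
             seed = if (is.null(seed)) NULL else child_seed(seed, "sepav", kk))
  })
}

sepav_pool <- function(cvs, penalty_rule, require_majority, imps) {
  m <- length(cvs)
  coefs <- t(vapply(cvs, function(cv)
    if (penalty_rule == "1se") cv$coef_1se else cv$coef_opt,
    numeric(ncol(imps$source$X) + 1)))
  active <- coefs[, -1, drop = FALSE] != 0
  selected <- if (require_majority) which(colMeans(active) >= 0.5)
              else which(colSums(active) > 0)
  avg <- colMeans(coefs)
  pooled_model(avg[1], avg[-1], selected,
               if (require_majority) "SepAvF" else "SepAv",
               penalty_rule = penalty_rule,
               info = list(active_freq = colMeans(active)))
}

#' Stack the completed datasets with observation weights
#'
#' Concatenates the m completions into one long dataset. With uniform
#' weighting every row gets weight 1/m, so each subject contributes total
#' weight one. With missingness weighting, row weight is
#' `(1/m) * (number of non-missing covariates of the subject in the source
#' data) / p`, down-weighting subjects with more imputed values.
#'
#' @param imps an `imputation_set`.
#' @param weighting `"uniform"` or `"missingness"`.
#' @return a `stacked_data`: `X`, `y`, `subject_id`, `row_weight`.
#' @export
make_stack <- function(imps, weighting = c("uniform", "missingness")) {
  weighting <- match.arg(weighting)
  n <- length(imps$source$y)
  p <- ncol(imps$source$X)
  X <- do.call(rbind, lapply(imps$completed, function(d) d$X))
  y <- rep(imps$source$y, imps$m)
  subject_id <- rep(seq_len(n), imps$m)
  w_subj <- if (weighting == "uniform") rep(1 / imps$m, n)
            else (1 / imps$m) * (p - rowSums(is.na(imps$source$X))) / p
  structure(list(X = X, y = y, subject_id = subject_id,
                 row_weight = rep(w_subj, imps$m), weighting = weighting,
                 m = imps$m),
            class = "stacked_data")
}

#' Lasso on the stacked imputed data
#'
#' Builds the stack, runs a single cross-validated lasso with the row
#' weights and subject-grouped fold assignment (a subject's m rows are held
#' out together), and returns the coefficient vector at the chosen penalty.
#' `Stack` uses uniform 1/m weights, `StackW` the missingness weights.
#'
#' @inheritParams select_sepav
#' @param weighting `"uniform"` (Stack) or `"missingness"` (StackW).
#' @return a [pooled_model()].
#' @export
select_stacked <- function(imps, weighting = c("uniform", "missingness"),
                           penalty_rule = c("1se", "optimal"), seed = NULL,
                           k = 10) {
  weighting <- match.arg(weighting)
  penalty_rule <- match.arg(penalty_rule)
  st <- make_stack(imps, weighting)
  cv <- lasso_cv(st$X, st$y, weights = st$row_weight, k = k,
                 group_ids = st$subject_id, seed = seed)
  stacked_pool(cv, penalty_rule, weighting)
}

stacked_pool <- function(cv, penalty_rule, weighting) {
  co <- if (penalty_rule == "1se") cv$coef_1se else cv$coef_opt
  pooled_model(co[1], co[-1], which(co[-1] != 0),
               if (weighting == "uniform") "Stack" else "StackW",
               penalty_rule = penalty_rule)
}

#' Reference models: FULL and TrueC
#'
#' Unpenalized logistic fits on the stacked data with uniform 1/m weights:
#' `FULL` uses all covariates, `TrueC` only the truly predictive ones
#' (simulation settings only, where the true set is known).
#'
#' @param imps an `imputation_set`.
#' @param which `"FULL"` or `"TrueC"`.
#' @param true_idx indices of the true covariates (required for TrueC).
#' @return a [pooled_model()].
#' @export
fit_reference <- function(imps, which = c("FULL", "TrueC"), true_idx = NULL) {
  which <- match.arg(which)
  p <- ncol(imps$source$X)
  sel <- if (which == "FULL") seq_len(p) else {
    if (is.null(true_idx)) stop("TrueC requires true_idx")
    sort(as.integer(true_idx))
  }
  st <- make_stack(imps, "uniform")
  f <- irls_logit(cbind(1, st$X[, sel, drop = FALSE]), st$y, w = st$row_weight)
  if (!f$converged || f$separated)
    stop(condition_convergence_error(paste("separation in", which, "fit")))
  slopes <- numeric(p)
  slopes[sel] <- f$coef[-1]
  pooled_model(f$coef[1], slopes, sel, which)
}
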