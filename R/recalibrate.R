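#' Recalibration of over-shrunk penalized models
#'
#' Models chosen with the 1-se penalty are deliberately over-shrunk; the two
#' recalibration schemes correct this on the same multiply imputed data used
#' for derivation. *Score* recalibration regresses the outcome on the
#' model's linear predictor `Z = intercept + X beta` and rescales every
#' slope by the common factor `gamma1` (new intercept
#' `gamma0 + gamma1 * intercept`), preserving the relative effects and the
#' prediction ranking. *Refit* recalibration refits the selected variables
#' by unpenalized maximum likelihood. For separate-imputation methods the
#' recalibration model is fit on each completion and the coefficients
#' averaged; for stacked methods it is fit once on the weighted stack.
#' Models derived with the optimal penalty are not recalibrated — their
#' shrinkage is already tuned — and requesting it is an error.
#'
#' @param model a [pooled_model()] with `penalty_rule != "optimal"`.
#' @param data the derivation data: an `imputation_set` (separate methods)
#'   or a `stacked_data` (stacked methods).
#' @return a recalibrated [pooled_model()]; score recalibration stores the
#'   fitted `gamma` in `info`.
#' @export
recalibrate_by_score <- function(model, data) {
  check_recalibratable(model)
  if (length(model$selected) < 1) stop("model has no selected covariates")
  gammas <- if (inherits(data, "imputation_set")) {
    g <- vapply(data$completed, function(d) {
      Z <- model$intercept + drop(d$X %*% model$slopes)
      score_gamma(Z, d$y)
    }, numeric(2))
    rowMeans(g)
  } else if (inherits(data, "stacked_data")) {
    Z <- model$intercept + drop(data$X %*% model$slopes)
    score_gamma(Z, data$y, data$row_weight)
  } else stop("data must be an imputation_set or stacked_data")
  if (any(!is.finite(gammas))) {
    warning("degenerate score; recalibration skipped")
    return(model)
  }
  pooled_model(gammas[1] + gammas[2] * model$intercept,
               gammas[2] * model$slopes, model$selected, model$method,
               penalty_rule = model$penalty_rule, recalibration = "score",
               info = c(model$info, list(gamma = gammas)))
}

score_gamma <- function(Z, y, w = NULL) {
  if (sd(Z) < 1e-12) return(c(NA_real_, NA_real_))
  irls_logit(cbind(1, Z), y, w = w)$coef
}

#' @rdname recalibrate_by_score
#' @export
recalibrate_by_refit <- function(model, data) {
  check_recalibratable(model)
  sel <- model$selected
  if (length(sel) < 1) stop("model has no selected covariates")
  p <- length(model$slopes)
  if (inherits(data, "imputation_set")) {
    co <- pooled_refit(data, sel)
  } else if (inherits(data, "stacked_data")) {
    f <- irls_logit(cbind(1, data$X[, sel, drop = FALSE]), data$y,
                    w = data$row_weight)
    if (!f$converged || f$separated)
      stop(condition_convergence_error("separation in recalibration refit"))
    co <- numeric(p + 1)
    co[c(1, 1 + sel)] <- f$coef
  } else stop("data must be an imputation_set or stacked_data")
  pooled_model(co[1], co[-1], sel, model$method,
               penalty_rule = model$penalty_rule, recalibration = "refit",
               info = model$info)
}

check_recalibratable <- function(model) {
  stopifnot(inherits(model, "pooled_model"))
  if (identical(model$penalty_rule, "optimal"))
    stop("recalibration is not offered for optimal-penalty models")
  invisible(model)
}
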