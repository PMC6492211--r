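#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a randomly chosen event receives a higher prediction
#' than a randomly chosen non-event, with ties counted 1/2; computed from
#' midranks.
#'
#' @param pred numeric predictions (any monotone score).
#' @param y binary 0/1 outcome with both classes present.
#' @return scalar AUC in `[0, 1]`.
#' @export
auc <- function(pred, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(pred)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#' @param pred predicted probabilities in `[0, 1]`.
#' @param y binary 0/1 outcome.
#' @return scalar in `[0, 1]`.
#' @export
brier <- function(pred, y) {
  stopifnot(all(pred >= 0 & pred <= 1))
  mean((pred - y)^2)
}

#' External validation of a pooled model
#'
#' Generates a fresh, fully observed validation dataset from the mechanism,
#' predicts with the pooled coefficients, and records discrimination (AUC),
#' overall accuracy (Brier score), and selection performance: the numbers of
#' selected truly predictive and noise covariates.
#'
#' @param model a [pooled_model()].
#' @param mech the [build_mechanism()] the model was derived under.
#' @param n_val validation sample size (default 5000).
#' @param seed optional integer seed for the validation draw.
#' @param val optional pre-generated `complete_data` to validate on (then
#'   `n_val`/`seed` are ignored) — lets several models share one set.
#' @return a `performance_record` list: `auc`, `brier`, `n_true_selected`,
#'   `n_noise_selected`, `n_selected`, `method`, `penalty_rule`,
#'   `recalibration`.
#' @export
evaluate_external <- function(model, mech, n_val = 5000, seed = NULL,
                              val = NULL) {
  stopifnot(inherits(model, "pooled_model"), inherits(mech, "mechanism_spec"))
  if (is.null(val)) val <- generate_complete(mech, n_val, seed = seed)
  pred <- predict(model, val)
  structure(list(
    auc = auc(pred, val$y),
    brier = brier(pred, val$y),
    n_true_selected = length(intersect(model$selected, mech$true_idx)),
    n_noise_selected = length(setdiff(model$selected, mech$true_idx)),
    n_selected = length(model$selected),
    method = model$method, penalty_rule = model$penalty_rule,
    recalibration = model$recalibration
  ), class = "performance_record")
}

#' Events per variable of a dataset
#'
#' The smaller outcome-class count divided by the number of estimated
#' parameters (p covariates plus intercept).
#' @param y binary outcome.
#' @param p number of covariates.
#' @return scalar EPV.
#' @export
events_per_variable <- function(y, p) {
  min(sum(y == 1), sum(y == 0)) / (p + 1)
}

#' Summarize replicate-level performance records per method variant
#'
#' Aggregates a tidy records data frame (as produced by [run_scenario()] or
#' [records_to_df()]) by method variant: means and empirical SDs of AUC and
#' Brier score, normal-approximation confidence-interval half-widths
#' `1.96 * SD / sqrt(reps)`, mean selected-true/noise counts, replicate and
#' failure counts.
#'
#' @param records data frame with columns `method`, `penalty_rule`,
#'   `recalibration`, `auc`, `brier`, `n_true_selected`, `n_noise_selected`,
#'   and optionally `failed` (logical).
#' @return a data frame, one row per method variant.
#' @export
summarize_scenario <- function(records) {
  stopifnot(nrow(records) >= 2)
  if (is.null(records$failed)) records$failed <- FALSE
  key <- interaction(records$method, records$penalty_rule,
                     records$recalibration, drop = TRUE)
  ok <- !records$failed
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    g <- records[key == lv & ok, , drop = FALSE]
    nfail <- sum(key == lv & !ok)
    if (nrow(g) == 0)
      return(data.frame(method = sub("\\..*", "", lv),
                        penalty_rule = NA, recalibration = NA,
                        reps = 0L, failures = nfail,
                        auc_mean = NA_real_, auc_sd = NA_real_,
                        auc_ci_halfwidth = NA_real_,
                        brier_mean = NA_real_, brier_sd = NA_real_,
                        brier_ci_halfwidth = NA_real_,
                        true_mean = NA_real_, noise_mean = NA_real_))
    r <- nrow(g)
    data.frame(method = g$method[1], penalty_rule = g$penalty_rule[1],
               recalibration = g$recalibration[1],
               reps = r, failures = nfail,
               auc_mean = mean(g$auc), auc_sd = sd(g$auc),
               auc_ci_halfwidth = 1.96 * sd(g$auc) / sqrt(r),
               brier_mean = mean(g$brier), brier_sd = sd(g$brier),
               brier_ci_halfwidth = 1.96 * sd(g$brier) / sqrt(r),
               true_mean = mean(g$n_true_selected),
               noise_mean = mean(g$n_noise_selected))
  }))
  rownames(out) <- NULL
  out
}
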