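#' Enhanced-bootstrap optimism correction with re-imputation
#'
#' Internal validation of a complete model-building pipeline (imputation +
#' selection) on incomplete data. The pipeline is first run on the original
#' data: the m completed datasets `Imp_1..m` and the resulting pooled model
#' give the *apparent* performance (metric averaged over the m completions).
#' Then, B times: subjects are resampled with replacement from the
#' *incomplete* data, the resample is re-imputed, the entire pipeline is
#' re-run, and the bootstrap model is evaluated on its own bootstrap
#' imputations (`apparent_b`) and on the original imputations (`test_b`).
#' The optimism is the mean of `apparent_b - test_b` over bootstrap samples
#' (each already averaged over imputations), and the corrected performance
#' is `apparent - optimism`. Pipeline failures inside a bootstrap replicate
#' are logged, skipped, and reflected in the effective B.
#'
#' @param data an `incomplete_data`.
#' @param pipeline function `(imps, seed)` returning a [pooled_model()];
#'   must be deterministic given its seed.
#' @param B bootstrap resamples (default 100).
#' @param m imputations per run (default 10).
#' @param cycles,donors chained-equation settings passed to
#'   [impute_chained()].
#' @param metrics character subset of `c("auc", "brier")`.
#' @param seed master seed; all stages consume child seeds.
#' @return an `optimism_estimate`: per metric `apparent`, `optimism`,
#'   `corrected` (`= apparent - optimism` exactly), plus `B`, `B_effective`,
#'   and the per-replicate table `per_b`.
#' @export
optimism_correct <- function(data, pipeline, B = 100, m = 10, cycles = 5,
                             donors = 5, metrics = c("auc", "brier"),
                             seed = 1L) {
  stopifnot(inherits(data, "incomplete_data"), B >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE)
  imps0 <- impute_chained(data, m = m, cycles = cycles, donors = donors,
                          seed = child_seed(seed, "orig-imp"))
  model0 <- pipeline(imps0, child_seed(seed, "orig-fit"))
  apparent <- metric_over_imps(model0, imps0, metrics)
  n <- length(data$y)
  per_b <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(child_seed(seed, "boot-idx", b))
    idx <- sample.int(n, n, replace = TRUE)
    datb <- subset_incomplete(data, idx)
    res <- tryCatch({
      impb <- impute_chained(datb, m = m, cycles = cycles, donors = donors,
                             seed = child_seed(seed, "boot-imp", b))
      modelb <- pipeline(impb, child_seed(seed, "boot-fit", b))
      list(apparent_b = metric_over_imps(modelb, impb, metrics),
           test_b = metric_over_imps(modelb, imps0, metrics))
    }, mivarsel_convergence_error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    per_b[[b]] <- data.frame(b = b, metric = metrics,
                             apparent_b = res$apparent_b,
                             test_b = res$test_b)
  }
  per_b <- do.call(rbind, per_b)
  if (is.null(per_b))
    stop(condition_convergence_error("all bootstrap replicates failed"))
  est <- lapply(metrics, function(mt) {
    g <- per_b[per_b$metric == mt, , drop = FALSE]
    opt <- mean(g$apparent_b - g$test_b)
    list(apparent = apparent[[mt]], optimism = opt,
         corrected = apparent[[mt]] - opt)
  })
  names(est) <- metrics
  structure(list(estimates = est, B = B, B_effective = B - failed,
                 per_b = per_b, model = model0),
            class = "optimism_estimate")
}

metric_over_imps <- function(model, imps, metrics) {
  vals <- sapply(imps$completed, function(d) {
    pred <- predict(model, d)
    c(auc = auc(pred, d$y), brier = brier(pred, d$y))
  })
  out <- rowMeans(vals)[metrics]
  names(out) <- metrics
  out
}

subset_incomplete <- function(data, idx) {
  structure(list(X = data$X[idx, , drop = FALSE], y = data$y[idx],
                 mask = data$mask[idx, , drop = FALSE],
                 alpha0 = data$alpha0, miss = data$miss,
                 mechanism = data$mechanism),
            class = "incomplete_data")
}

#' @exportS3Method base::print
print.optimism_estimate <- function(x, ...) {
  cat(sprintf("optimism_estimate (B = %d, effective %d):\n",
              x$B, x$B_effective))
  for (mt in names(x$estimates)) {
    e <- x$estimates[[mt]]
    cat(sprintf("  %-6s apparent %.4f  optimism %+.4f  corrected %.4f\n",
                mt, e$apparent, e$optimism, e$corrected))
  }
  invisible(x)
}
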