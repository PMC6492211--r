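test_that("backward elimination agrees with an exhaustive greedy oracle", {
  oracle_backward <- function(X, y) {
    active <- seq_len(ncol(X))
    aic_of <- function(cols) {
      if (length(cols) == 0) AIC(glm(y ~ 1, family = binomial))
      else AIC(glm(y ~ X[, cols, drop = FALSE], family = binomial))
    }
    current <- aic_of(active)
    repeat {
      if (length(active) == 0) break
      cand <- vapply(seq_along(active),
                     function(i) aic_of(active[-i]), numeric(1))
      if (min(cand) >= current) break
      current <- min(cand)
      active <- active[-which.min(cand)]
    }
    sort(active)
  }
  for (s in 1:8) {
    d <- toy_logit(n = 150, p = 5, beta = c(1.2, -0.8, 0, 0, 0), seed = 40 + s)
    expect_equal(backward_eliminate_aic(d$X, d$y), oracle_backward(d$X, d$y))
  }
})

test_that("backward elimination keeps strong predictors and can keep all", {
  # one covariate with log-OR 2 among pure noise is retained essentially always
  kept <- vapply(1:20, function(s) {
    d <- toy_logit(n = 2000, p = 5, beta = c(2, 0, 0, 0, 0), seed = 60 + s)
    1 %in% backward_eliminate_aic(d$X, d$y)
  }, logical(1))
  expect_gte(mean(kept), 0.95)
  # all-strong covariates: no removal decreases AIC, everything stays
  d <- toy_logit(n = 1500, p = 4, beta = c(1.5, -1.5, 1.5, -1.5), seed = 81)
  expect_equal(backward_eliminate_aic(d$X, d$y), 1:4)
})

test_that("separated data raise a convergence error", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_error(backward_eliminate_aic(cbind(x), y),
               class = "mivarsel_convergence_error")
})

test_that("bootstrap inclusion frequencies tally the stored fits", {
  imps <- sim_imps(n = 120, miss = 0.2, m = 2, seed = 51)
  fr <- bootstrap_inclusion(imps, B = 3, base = "lasso_1se", seed = 5)
  expect_equal(fr$freq, colMeans(fr$fits))       # recount oracle
  expect_true(all(fr$freq >= 0 & fr$freq <= 1))
  expect_equal(nrow(fr$fits) + fr$failures, fr$m * fr$B)
  # single fit: frequencies are 0 or 1
  imps1 <- make_imputation_set(list(imps$completed[[1]]$X), imps$source$y)
  fr1 <- bootstrap_inclusion(imps1, B = 1, base = "lasso_1se", seed = 6)
  expect_true(all(fr1$freq %in% c(0, 1)))
})

test_that("frequency selection is inclusive at the threshold and pools by averaging", {
  imps <- sim_imps(n = 150, miss = 0.2, m = 2, seed = 52)
  p <- ncol(imps$source$X)
  freq <- rep(0, p); freq[c(8, 9)] <- c(0.5, 0.8); freq[10] <- 0.49
  fr <- structure(list(freq = freq, fits = NULL, failures = 0L, B = 10,
                       m = 2, base = "lasso_1se"), class = "inclusion_freq")
  model <- select_by_frequency(fr, imps, threshold = 0.5, method = "BLaF")
  expect_equal(model$selected, c(8L, 9L))        # 0.50 in, 0.49 out
  # pooled slopes are the arithmetic mean of the per-completion ML fits
  fits <- lapply(imps$completed, function(d)
    coef(glm(d$y ~ d$X[, c(8, 9)], family = binomial)))
  avg <- rowMeans(do.call(cbind, fits))
  expect_equal(model$intercept, unname(avg[1]), tolerance = 1e-6)
  expect_equal(unname(model$slopes[c(8, 9)]), unname(avg[2:3]),
               tolerance = 1e-6)
  # empty selection: intercept-only model
  fr0 <- structure(list(freq = rep(0, p), fits = NULL, failures = 0L,
                        B = 10, m = 2, base = "aic_backward"),
                   class = "inclusion_freq")
  expect_message(m0 <- select_by_frequency(fr0, imps, method = "BBeF"),
                 "empty")
  expect_equal(m0$selected, integer(0))
  expect_true(all(m0$slopes == 0))
})

test_that("separate-imputation lasso pools by averaging all m coefficient vectors", {
  imps <- sim_imps(n = 200, miss = 0.3, m = 3, seed = 53)
  sep <- select_sepav(imps, "1se", seed = 77)
  # recomputation oracle via the documented per-completion seed scheme
  coefs <- t(sapply(seq_len(3), function(k) {
    d <- imps$completed[[k]]
    lasso_cv(d$X, d$y, k = 10, seed = child_seed(77, "sepav", k))$coef_1se
  }))
  expect_equal(sep$intercept, mean(coefs[, 1]))
  active_union <- which(colSums(coefs[, -1] != 0) > 0)
  expect_equal(sep$selected, active_union)
  expect_equal(sep$slopes[active_union], colMeans(coefs[, -1])[active_union])
  # zeros from non-selecting completions are part of the average
  once <- which(colSums(coefs[, -1] != 0) == 1)
  if (length(once) > 0) {
    j <- once[1]
    expect_equal(sep$slopes[j], sum(coefs[, j + 1]) / 3)
  }
  # majority variant is nested in the union variant
  sepf <- select_sepav(imps, "1se", require_majority = TRUE, seed = 77)
  expect_true(all(sepf$selected %in% sep$selected))
  expect_equal(sepf$method, "SepAvF")
})

test_that("identical completions collapse SepAv and SepAvF to one lasso", {
  # degenerate multiple imputation: every completion carries the same data,
  # so identical per-completion fits must pool to the single-dataset lasso
  d <- toy_logit(n = 150, p = 6, seed = 54)
  imps <- make_imputation_set(list(d$X, d$X, d$X), d$y)
  cv <- lasso_cv(d$X, d$y, seed = 5)
  a <- mivarsel:::sepav_pool(list(cv, cv, cv), "1se", FALSE, imps)
  b <- mivarsel:::sepav_pool(list(cv, cv, cv), "1se", TRUE, imps)
  expect_equal(a$selected, b$selected)
  expect_equal(a$slopes, b$slopes)
  expect_equal(a$intercept, cv$coef_1se[1])
  expect_equal(a$slopes, cv$coef_1se[-1])
  # with independent fold draws per completion the pooled slopes are still
  # the average of the per-completion coefficient vectors
  s <- select_sepav(imps, "1se", FALSE, seed = 5)
  coefs <- sapply(1:3, function(k)
    lasso_cv(d$X, d$y, seed = child_seed(5, "sepav", k))$coef_1se)
  expect_equal(s$intercept, mean(coefs[1, ]))
  expect_equal(s$slopes[s$selected], rowMeans(coefs[-1, ])[s$selected])
})

test_that("stack weights follow the missingness formula", {
  inc <- toy_incomplete(n = 30, p = 5, miss_cols = c(1, 3), frac = 0.4,
                        seed = 55)
  imps <- impute_chained(inc, m = 10, seed = 1)
  st <- make_stack(imps, "missingness")
  expect_equal(nrow(st$X), 300)
  expect_equal(st$subject_id, rep(1:30, 10))
  n_obs <- 5 - rowSums(is.na(inc$X))
  expect_equal(st$row_weight, rep((1 / 10) * n_obs / 5, 10))
  # fully observed subject at m = 10: weight 1/10
  full_subj <- which(n_obs == 5)[1]
  expect_equal(st$row_weight[full_subj], 0.1)
  expect_true(all(st$row_weight > 0 & st$row_weight <= 0.1))
  # uniform weighting: all rows 1/m; equals missingness weights when complete
  stu <- make_stack(imps, "uniform")
  expect_true(all(stu$row_weight == 0.1))
  # worked example: 12 of 15 covariates observed, m = 10 -> 0.08
  expect_equal((1 / 10) * (12 / 15), 0.08)
})

test_that("stacking m identical copies reproduces the single-dataset lasso", {
  d <- toy_logit(n = 150, p = 6, seed = 56)
  imps <- make_imputation_set(list(d$X, d$X, d$X), d$y)
  stacked <- select_stacked(imps, "uniform", "1se", seed = 12)
  single <- lasso_cv(d$X, d$y, seed = 12)
  expect_equal(stacked$intercept, single$coef_1se[1], tolerance = 1e-6)
  expect_equal(stacked$slopes, single$coef_1se[-1], tolerance = 1e-6)
  # StackW on fully observed data is identical to Stack
  sw <- select_stacked(imps, "missingness", "1se", seed = 12)
  expect_equal(sw$slopes, stacked$slopes)
})

test_that("reference models fit the stacked data by maximum likelihood", {
  mech <- build_mechanism("one")
  imps <- sim_imps(n = 300, miss = 0.1, m = 2, seed = 57, mech = mech)
  truec <- fit_reference(imps, "TrueC", true_idx = mech$true_idx)
  expect_equal(truec$selected, 4:10)
  expect_true(all(truec$slopes[-(4:10)] == 0))
  full <- fit_reference(imps, "FULL")
  expect_equal(full$selected, 1:15)
  # on a single fully observed copy, FULL is the plain ML fit
  d <- toy_logit(n = 200, p = 4, seed = 58)
  imps1 <- make_imputation_set(list(d$X), d$y)
  f <- fit_reference(imps1, "FULL")
  oracle <- coef(glm(d$y ~ d$X, family = binomial))
  expect_equal(c(f$intercept, f$slopes), unname(oracle), tolerance = 1e-7)
  expect_error(fit_reference(imps1, "TrueC"), "true_idx")
})
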