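test_that("the penalty path starts at the null model and satisfies KKT", {
  d <- toy_logit(n = 250, p = 7, seed = 31)
  w <- runif(250, 0.5, 2)
  path <- fit_path(d$X, d$y, weights = w)
  # full shrinkage: all slopes zero, intercept is the weighted logit of mean(y)
  expect_true(all(path$beta[, 1] == 0))
  expect_equal(path$a0[1], qlogis(weighted.mean(d$y, w)), tolerance = 1e-6)
  expect_true(all(diff(path$lambda) < 0))
  # subgradient conditions at every grid point
  expect_lt(max(kkt_violation(path, d$X, d$y, w)), 1e-5)
})

test_that("the unpenalized end of the path matches the ML oracle", {
  d <- toy_logit(n = 400, p = 5, seed = 32)
  path <- fit_path(d$X, d$y)
  p0 <- fit_path(d$X, d$y, lambda = c(path$lambda, 0))
  co <- path_coef(p0, 0)
  oracle <- coef(glm(d$y ~ d$X, family = binomial))
  expect_equal(co, unname(oracle), tolerance = 1e-4)
})

test_that("weighted fits are invariant to row duplication with halved weights", {
  d <- toy_logit(n = 150, p = 6, seed = 33)
  w <- runif(150, 0.5, 2)
  path <- fit_path(d$X, d$y, weights = w)
  dup <- fit_path(rbind(d$X, d$X), c(d$y, d$y), weights = c(w, w) / 2,
                  lambda = path$lambda)
  expect_equal(as.matrix(path$beta), as.matrix(dup$beta), tolerance = 1e-6)
  expect_equal(path$a0, dup$a0, tolerance = 1e-6)
  # all-equal weights reproduce the unweighted fit
  unw <- fit_path(d$X, d$y)
  eqw <- fit_path(d$X, d$y, weights = rep(2, 150), lambda = unw$lambda)
  expect_equal(as.matrix(unw$beta), as.matrix(eqw$beta), tolerance = 1e-8)
})

test_that("fold assignment partitions rows, stratifies, and respects groups", {
  set.seed(34)
  y_subj <- rbinom(60, 1, 0.4)
  ids <- rep(1:60, times = 5)
  y <- y_subj[ids]
  fid <- assign_folds(y, k = 10, group_ids = ids, seed = 9)
  expect_setequal(unique(fid), 1:10)
  # all rows of a subject share one fold
  expect_true(all(tapply(fid, ids, function(v) length(unique(v))) == 1))
  # stratification: each fold has both classes at the subject level
  subj_fold <- tapply(fid, ids, unique)
  expect_true(all(table(y_subj, subj_fold) > 0))
})

test_that("cross-validated deviance matches direct recomputation", {
  d <- toy_logit(n = 200, p = 5, seed = 35)
  cv <- cv_curve(d$X, d$y, k = 5, seed = 41)
  expect_equal(cv$cvm, colMeans(cv$fold_dev))
  expect_equal(cv$cvse, apply(cv$fold_dev, 2, sd) / sqrt(5))
  expect_true(all(cv$cvse >= 0))
  # independent recomputation of fold 1 from a fresh fit on its training rows
  tr <- cv$foldid != 1
  g <- glmnet::glmnet(d$X[tr, ], d$y[tr], family = "binomial",
                      lambda = cv$lambda, standardize = TRUE, thresh = 1e-10)
  ph <- predict(g, d$X[!tr, ], type = "response")
  ph <- pmin(pmax(ph, 1e-15), 1 - 1e-15)
  yte <- d$y[!tr]
  dev1 <- colMeans(-2 * (yte * log(ph) + (1 - yte) * log(1 - ph)))
  expect_equal(cv$fold_dev[1, ], unname(dev1), tolerance = 1e-7)
})

test_that("identical folds of identical data give zero deviance spread", {
  d <- toy_logit(n = 80, p = 4, seed = 36)
  k <- 4
  Xr <- do.call(rbind, replicate(k, d$X, simplify = FALSE))
  yr <- rep(d$y, k)
  copy_id <- rep(1:k, each = 80)
  cv <- cv_curve(Xr, yr, k = k, group_ids = copy_id, seed = 3)
  expect_lt(max(cv$cvse), 1e-10)
})

test_that("penalty choice follows the 1-se convention", {
  # flat curve: everything within one se, pick the largest penalty
  flat <- structure(list(lambda = c(1, 0.5, 0.1), cvm = c(1.3, 1.3, 1.3),
                         cvse = c(0.05, 0.05, 0.05)), class = "cv_curve")
  ch <- choose_penalty(flat)
  expect_equal(ch$lambda_1se, 1)
  expect_equal(ch$lambda_opt, 1)   # ties break toward the larger penalty
  # strictly convex curve with negligible se: the two rules agree
  lam <- exp(seq(0, -4, length.out = 30))
  cvm <- (log(lam) + 2)^2 + 1
  convex <- structure(list(lambda = lam, cvm = cvm,
                           cvse = rep(1e-9, 30)), class = "cv_curve")
  ch2 <- choose_penalty(convex)
  expect_equal(ch2$i_1se, ch2$i_opt)
  # the ordering invariant on real fits
  for (s in 1:5) {
    d <- toy_logit(n = 120, p = 6, seed = 36 + s)
    ch3 <- choose_penalty(cv_curve(d$X, d$y, seed = s))
    expect_gte(ch3$lambda_1se, ch3$lambda_opt)
  }
})

test_that("degenerate single-class folds keep the deviance finite", {
  set.seed(37)
  X <- matrix(rnorm(60), 30, 2)
  y <- c(rep(1, 27), rep(0, 3))
  cv <- suppressWarnings(cv_curve(X, y, k = 3, seed = 2))
  expect_true(all(is.finite(cv$cvm)))
})
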