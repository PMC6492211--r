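test_that("chained imputation preserves observed cells and fills all holes", {
  inc <- toy_incomplete(n = 200, miss_cols = c(1, 3), frac = 0.25, seed = 21,
                        binary_col = 3)
  imps <- impute_chained(inc, m = 4, seed = 99)
  obs <- !is.na(inc$X)
  for (k in 1:4) {
    Xc <- imps$completed[[k]]$X
    expect_false(anyNA(Xc))
    expect_identical(Xc[obs], inc$X[obs])     # bit-exact on observed cells
    expect_identical(imps$completed[[k]]$y, inc$y)
  }
  # continuous imputations are observed donor values (PMM property)
  mis1 <- is.na(inc$X[, 1])
  donors <- inc$X[!mis1, 1]
  for (k in 1:4)
    expect_true(all(imps$completed[[k]]$X[mis1, 1] %in% donors))
  # binary imputations stay binary
  mis3 <- is.na(inc$X[, 3])
  for (k in 1:4)
    expect_true(all(imps$completed[[k]]$X[mis3, 3] %in% c(0, 1)))
})

test_that("imputation is seed-reproducible and seed-sensitive", {
  inc <- toy_incomplete(seed = 22)
  a <- impute_chained(inc, m = 2, seed = 7)
  b <- impute_chained(inc, m = 2, seed = 7)
  c <- impute_chained(inc, m = 2, seed = 8)
  expect_identical(a$completed[[1]]$X, b$completed[[1]]$X)
  expect_identical(a$completed[[2]]$X, b$completed[[2]]$X)
  expect_false(identical(a$completed[[1]]$X, c$completed[[1]]$X))
  # distinct completions differ on the missing cells
  expect_false(identical(a$completed[[1]]$X, a$completed[[2]]$X))
})

test_that("a dataset without missing values imputes to identical copies", {
  set.seed(23)
  X <- matrix(rnorm(60), 20, 3)
  inc <- structure(list(X = X, y = rbinom(20, 1, 0.5),
                        mask = matrix(0L, 20, 3), alpha0 = NA_real_,
                        miss = 0, mechanism = NA),
                   class = "incomplete_data")
  imps <- impute_chained(inc, m = 3, seed = 1)
  for (k in 1:3) expect_identical(imps$completed[[k]]$X, X)
})

test_that("MCAR imputation recovers the pre-deletion mean", {
  set.seed(24)
  n <- 600
  X <- cbind(rnorm(n), rnorm(n))
  X[, 1] <- 0.8 * X[, 2] + rnorm(n, sd = 0.6)
  y <- rbinom(n, 1, plogis(X[, 1]))
  full_mean <- mean(X[, 1])
  Xm <- X
  drop_idx <- sample(n, round(0.2 * n))
  Xm[drop_idx, 1] <- NA
  inc <- structure(list(X = Xm, y = y, mask = NULL, alpha0 = NA, miss = 0.2,
                        mechanism = NA), class = "incomplete_data")
  imps <- impute_chained(inc, m = 10, seed = 31)
  imp_means <- vapply(imps$completed, function(d) mean(d$X[, 1]), numeric(1))
  expect_equal(mean(imp_means), full_mean, tolerance = 0.08)
})

test_that("pmm_draw degenerate pools behave as specified", {
  set.seed(25)
  n <- 60
  D <- cbind(1, rnorm(n))
  mis <- c(rep(FALSE, 50), rep(TRUE, 10))
  # constant observed target: the only donor value is c
  tgt <- rep(3.5, n); tgt[mis] <- NA_real_
  tgt[mis] <- 0
  expect_true(all(pmm_draw(tgt, D, mis)[mis] == 3.5))
  # donors = 1 picks the single nearest-prediction observed value
  tgt2 <- D[, 2] * 2 + rnorm(n, sd = 0.1)
  filled <- pmm_draw(tgt2, D, mis, donors = 1)
  expect_true(all(filled[mis] %in% tgt2[!mis]))
  # imputations never leave the observed range
  rng <- range(tgt2[!mis])
  for (r in 1:50) {
    f <- pmm_draw(tgt2, D, mis, donors = 5)
    expect_true(all(f[mis] >= rng[1] & f[mis] <= rng[2]))
  }
  expect_error(pmm_draw(tgt2, D, rep(TRUE, n)), "donors")
})

test_that("logistic_draw tracks the predictor and handles one-class targets", {
  set.seed(26)
  n <- 400
  x <- rnorm(n)
  D <- cbind(1, x)
  tgt <- rbinom(n, 1, plogis(3 * x))
  mis <- seq_len(n) > 300
  tgt_obs <- tgt; tgt_obs[mis] <- NA; tgt_obs[mis] <- 0
  filled <- logistic_draw(tgt, D, mis)
  expect_true(all(filled[mis] %in% c(0, 1)))
  # imputations recover the sign of the association
  expect_gt(cor(x[mis], filled[mis]), 0.3)
  # null design keeps the observed prevalence
  tgt0 <- rbinom(n, 1, 0.5)
  f0 <- replicate(30, mean(logistic_draw(tgt0, cbind(1, rnorm(n) * 0), mis)[mis]))
  expect_equal(mean(f0), mean(tgt0[!mis]), tolerance = 0.06)
  # one observed class imputes that class
  tgt1 <- rep(1, n)
  expect_message(f1 <- logistic_draw(tgt1, D, mis), "one-class")
  expect_true(all(f1[mis] == 1))
})

test_that("imputations can be written to disk with a manifest", {
  inc <- toy_incomplete(seed = 27)
  imps <- impute_chained(inc, m = 3, seed = 2)
  dir <- withr::local_tempdir()
  write_imputations(imps, dir)
  expect_true(file.exists(file.path(dir, "imp_002.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$m, 3)
  back <- read_dataset(file.path(dir, "imp_001.csv"))
  expect_equal(unname(back$X), unname(imps$completed[[1]]$X))
})
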