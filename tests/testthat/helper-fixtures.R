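# Small in-code fixtures shared across the test files.

# logistic toy data with known coefficients
toy_logit <- function(n = 200, p = 6, beta = NULL, intercept = 0.2,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- c(1, -0.5, rep(0, p - 2))
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  list(X = X, y = y, beta = beta, intercept = intercept)
}

# incomplete_data with MCAR holes in the given columns
toy_incomplete <- function(n = 150, p = 5, miss_cols = c(1, 3), frac = 0.2,
                           seed = 1, binary_col = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (!is.null(binary_col)) X[, binary_col] <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(0.5 * X[, 1]))
  full <- X
  mask <- matrix(0L, n, p)
  for (j in miss_cols) {
    R <- rbinom(n, 1, frac)
    mask[, j] <- R
    X[R == 1, j] <- NA_real_
  }
  structure(list(X = X, y = y, mask = mask, alpha0 = NA_real_, miss = frac,
                 mechanism = NA, full = full),
            class = "incomplete_data")
}

# hand-built imputation_set from a list of covariate matrices sharing y
make_imputation_set <- function(X_list, y, source = NULL) {
  completed <- lapply(X_list, function(X)
    structure(list(X = X, y = y, mechanism = NA), class = "complete_data"))
  if (is.null(source))
    source <- structure(list(X = X_list[[1]], y = y,
                             mask = matrix(0L, nrow(X_list[[1]]),
                                           ncol(X_list[[1]])),
                             alpha0 = NA_real_, miss = 0, mechanism = NA),
                        class = "incomplete_data")
  structure(list(completed = completed, m = length(X_list), source = source),
            class = "imputation_set")
}

# imputation set from a simulated incomplete dataset
sim_imps <- function(n = 150, miss = 0.2, m = 3, seed = 11,
                     mech = build_mechanism("one")) {
  d <- generate_complete(mech, n, seed = seed)
  inc <- impose_mar(d, mech, miss, seed = seed + 1)
  impute_chained(inc, m = m, seed = seed + 2)
}
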