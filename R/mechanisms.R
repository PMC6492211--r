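#' Data-generating mechanisms for the simulation engine
#'
#' Two covariate-generating mechanisms for binary-outcome prediction studies.
#' Mechanism `"one"` draws 15 standard-normal covariates with a sparse
#' correlation structure (rho[1,10] = rho[2,6] = rho[7,14] = rho[9,13] = 0.5,
#' rho[4,8] = -0.7, rho[7,8] = 0.3, rho[11,12] = 0.7), dichotomizes
#' X2, X4, X5, X9, X10, X11, X12 at 0, and uses true log-odds coefficients
#' beta4 = -0.5, beta5 = beta6 = beta7 = 0.5, beta8 = beta9 = 1, beta10 = 1.5
#' (all others 0) with intercept -0.25, giving an outcome prevalence of about
#' 60%. Mechanism `"two"` extends it to 25 covariates with AR(1) correlation
#' (rho = 0.5 by variable order); X16--X25 are continuous noise. Missingness
#' is later imposed on the sets J = {2,5,7,8,12,14} (one) and
#' J = {2,5,7,8,12,14,16,17,19,23} (two).
#'
#' @param which `"one"` or `"two"`.
#' @return a `mechanism_spec` with fields `p`, `corr`, `binary_idx`, `beta`,
#'   `intercept`, `miss_idx`, `miss_slope`, `true_idx`.
#' @examples
#' mech <- build_mechanism("one")
#' mech$corr[11, 12]
#' @export
build_mechanism <- function(which = c("one", "two")) {
  which <- match.arg(which)
  binary_idx <- c(2L, 4L, 5L, 9L, 10L, 11L, 12L)
  beta15 <- numeric(15)
  beta15[4] <- -0.5
  beta15[5:7] <- 0.5
  beta15[8:9] <- 1
  beta15[10] <- 1.5
  if (which == "one") {
    p <- 15L
    corr <- diag(p)
    pairs <- cbind(i = c(1, 2, 7, 9, 4, 7, 11),
                   j = c(10, 6, 14, 13, 8, 8, 12),
                   rho = c(0.5, 0.5, 0.5, 0.5, -0.7, 0.3, 0.7))
    for (r in seq_len(nrow(pairs))) {
      corr[pairs[r, "i"], pairs[r, "j"]] <- pairs[r, "rho"]
      corr[pairs[r, "j"], pairs[r, "i"]] <- pairs[r, "rho"]
    }
    beta <- beta15
    miss_idx <- c(2L, 5L, 7L, 8L, 12L, 14L)
  } else {
    p <- 25L
    corr <- 0.5 ^ abs(outer(seq_len(p), seq_len(p), "-"))
    beta <- c(beta15, numeric(10))
    miss_idx <- c(2L, 5L, 7L, 8L, 12L, 14L, 16L, 17L, 19L, 23L)
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation matrix is not positive definite")
  structure(list(
    name = which, p = p, corr = corr, binary_idx = binary_idx,
    beta = beta, intercept = -0.25, miss_idx = miss_idx, miss_slope = 0.5,
    true_idx = which(beta != 0)
  ), class = "mechanism_spec")
}

#' @exportS3Method base::print
print.mechanism_spec <- function(x, ...) {
  cat(sprintf("mechanism_spec '%s': p = %d, %d true covariates, |J| = %d\n",
              x$name, x$p, length(x$true_idx), length(x$miss_idx)))
  invisible(x)
}

#' Generate a fully observed dataset from a mechanism
#'
#' Draws latent multivariate-normal covariates (mean 0, unit variance,
#' mechanism correlation), replaces the dichotomized columns by
#' `indicator(latent > 0)`, and draws the binary outcome from the logistic
#' model with the mechanism's coefficients applied to the transformed
#' covariates.
#'
#' @param mech a [build_mechanism()] object.
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @param keep_latent keep the pre-dichotomization draw as attribute
#'   `"latent"` (used by correlation diagnostics).
#' @return a `complete_data` list with `X` (n x p, binary columns in {0,1})
#'   and `y` (n binary outcomes).
#' @export
generate_complete <- function(mech, n, seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(mech, "mechanism_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n * mech$p), n, mech$p) %*% chol(mech$corr)
  X <- Z
  X[, mech$binary_idx] <- (Z[, mech$binary_idx] > 0) * 1
  eta <- mech$intercept + drop(X %*% mech$beta)
  y <- rbinom(n, 1L, plogis(eta))
  colnames(X) <- paste0("X", seq_len(mech$p))
  out <- structure(list(X = X, y = y, mechanism = mech$name),
                   class = "complete_data")
  if (keep_latent) attr(out, "latent") <- Z
  out
}

#' Solve the missingness-model intercept for a target missingness fraction
#'
#' Finds `alpha0` such that the average over subjects of
#' `plogis(alpha0 + offset_i)` equals `miss`. The mean is continuous and
#' strictly increasing in `alpha0`, so a bracketing root finder converges to
#' machine precision; the achieved mean is within 1e-10 of the target.
#'
#' @param miss target per-variable missingness fraction, in (0, 1).
#' @param offsets per-subject linear predictor excluding the intercept.
#' @return scalar `alpha0`.
#' @export
solve_alpha0 <- function(miss, offsets) {
  if (!is.numeric(miss) || length(miss) != 1 || miss <= 0 || miss >= 1)
    stop("'miss' must be a single value in (0, 1)")
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  f <- function(a) mean(plogis(a + offsets)) - miss
  hw <- max(abs(offsets)) + 1
  lo <- qlogis(miss) - hw
  hi <- qlogis(miss) + hw
  a0 <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  if (abs(f(a0)) > 1e-10)
    stop("alpha0 solver did not reach the requested tolerance")
  a0
}

#' Impose missing-at-random missingness on a complete dataset
#'
#' Each subject gets a single missingness probability
#' `p_i = plogis(alpha0 + 0.5 * sum_{k not in J} X_ki + 0.5 * y_i)` that
#' depends only on the always-observed covariates and the outcome; for each
#' variable `j` in the mechanism's missingness set J, the missing indicator
#' `R_ji` is drawn independently as Bernoulli(`p_i`). `alpha0` is re-solved
#' for every dataset from its own offsets so the average per-variable
#' missingness matches `miss`.
#'
#' @param data a `complete_data` generated under `mech`.
#' @param mech the generating [build_mechanism()].
#' @param miss target per-variable missingness fraction in (0, 1).
#' @param seed optional integer seed.
#' @return an `incomplete_data` list: `X` with `NA` entries, `y`, the 0/1
#'   indicator matrix `mask` (1 = missing), `alpha0`, `miss`, `mechanism`.
#' @export
impose_mar <- function(data, mech, miss, seed = NULL) {
  stopifnot(inherits(data, "complete_data"), inherits(mech, "mechanism_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$y)
  obs_idx <- setdiff(seq_len(mech$p), mech$miss_idx)
  offsets <- mech$miss_slope * rowSums(data$X[, obs_idx, drop = FALSE]) +
    mech$miss_slope * data$y
  alpha0 <- solve_alpha0(miss, offsets)
  p_i <- plogis(alpha0 + offsets)
  mask <- matrix(0L, n, mech$p)
  X <- data$X
  for (j in mech$miss_idx) {
    R <- rbinom(n, 1L, p_i)
    mask[, j] <- R
    X[R == 1L, j] <- NA_real_
  }
  structure(list(X = X, y = data$y, mask = mask, alpha0 = alpha0,
                 miss = miss, mechanism = mech$name),
            class = "incomplete_data")
}

#' @exportS3Method base::print
print.incomplete_data <- function(x, ...) {
  cat(sprintf("incomplete_data: n = %d, p = %d, %.1f%% of entries missing\n",
              length(x$y), ncol(x$X), 100 * mean(is.na(x$X))))
  invisible(x)
}

#' Fraction of complete cases (no missing covariate values)
#' @param data an `incomplete_data`.
#' @return fraction of subjects with zero missing covariates.
#' @export
complete_case_fraction <- function(data) {
  mean(rowSums(is.na(data$X)) == 0)
}

#' Write / read a (possibly incomplete) dataset as CSV with a JSON sidecar
#'
#' The CSV has a header row, the outcome in column `y`, and missing entries
#' as empty fields; the sidecar `<path>.json` records mechanism, miss, seed
#' and n so runs can be reproduced.
#'
#' @param data a `complete_data` or `incomplete_data`.
#' @param path CSV file path.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, meta = list()) {
  df <- data.frame(y = data$y, data$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  side <- c(list(n = length(data$y), p = ncol(data$X),
                 mechanism = data$mechanism %||% NA,
                 miss = data$miss %||% NA), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  y <- df$y
  if (anyNA(X)) {
    structure(list(X = X, y = y, mask = matrix(as.integer(is.na(X)),
                                               nrow(X), ncol(X)),
                   alpha0 = NA_real_, miss = NA_real_, mechanism = NA),
              class = "incomplete_data")
  } else {
    structure(list(X = X, y = y, mechanism = NA), class = "complete_data")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
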