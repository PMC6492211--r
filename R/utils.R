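#' @importFrom stats plogis qlogis rnorm rbinom rchisq runif sd uniroot predict
#' @importFrom stats weighted.mean aggregate qnorm
NULL

expit <- stats::plogis

#' Derive a child seed from a master seed
#'
#' Every stochastic stage of a pipeline consumes its own child seed derived
#' from the master seed and a stage label, so that full runs are reproducible
#' and replicate-level results do not depend on execution order.
#'
#' @param master integer master seed.
#' @param ... stage labels (coerced to character) identifying the consumer.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  cp <- utf8ToInt(key)
  h <- 0
  for (k in cp) h <- (h * 131 + k) %% 1009001
  as.integer((as.numeric(master) %% 2147483647 * 69091 + h * 7919 + 12345) %%
               2147483629 + 1)
}

clip_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

binomial_deviance <- function(y, p, w = NULL) {
  p <- clip_prob(p)
  ll <- y * log(p) + (1 - y) * log(1 - p)
  if (is.null(w)) -2 * mean(ll) else -2 * sum(w * ll) / sum(w)
}

#' Weighted logistic regression by iteratively reweighted least squares
#'
#' Internal workhorse for all unpenalized logistic fits (model refits,
#' recalibration, stacked-data reference models, backward elimination and the
#' imputation sub-models). Unlike [stats::glm()] it accepts fractional
#' observation weights silently (stacked multiply-imputed data uses weight
#' 1/m per row) and exposes an optional ridge penalty used as a fallback when
#' the likelihood is unbounded (complete or quasi-complete separation).
#'
#' @param X design matrix including an intercept column.
#' @param y binary 0/1 response.
#' @param w nonnegative observation weights (default all 1).
#' @param ridge ridge penalty added to all coefficients except the first
#'   (intercept) column; 0 for plain maximum likelihood.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   maximum absolute coefficient change.
#' @param start optional starting coefficient vector (warm start).
#' @return list with `coef`, `fitted`, `deviance`, `aic`, `cov` (inverse
#'   observed information), `converged`, and `separated` (TRUE when fitted
#'   probabilities hit the 0/1 boundary numerically).
#' @keywords internal
irls_logit <- function(X, y, w = NULL, ridge = 0, maxit = 60, tol = 1e-10,
                       start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(start)) {
    beta <- numeric(d)
    ybar <- weighted.mean(y, w)
    beta[1] <- qlogis(min(max(ybar, 1e-6), 1 - 1e-6))
  } else beta <- start
  pen <- if (ridge > 0) diag(c(0, rep(ridge, d - 1)), d) else NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wt <- w * mu * (1 - mu)
    wt <- pmax(wt, 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    XtW <- t(X * wt)
    A <- XtW %*% X
    if (!is.null(pen)) A <- A + pen
    beta_new <- tryCatch(drop(solve(A, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      # singular information: stabilize with a small ridge and continue
      A <- A + diag(1e-8 * max(diag(A)), d)
      beta_new <- drop(solve(A, XtW %*% z))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  separated <- any(mu[w > 0] < 1e-10) || any(mu[w > 0] > 1 - 1e-10)
  dev <- -2 * sum(w * (y * log(clip_prob(mu)) + (1 - y) * log(clip_prob(1 - mu))))
  wt <- pmax(w * mu * (1 - mu), 1e-12)
  A <- t(X * wt) %*% X
  if (!is.null(pen)) A <- A + pen
  covb <- tryCatch(solve(A), error = function(e) {
    solve(A + diag(1e-8 * max(diag(A)), d))
  })
  list(coef = beta, fitted = mu, deviance = dev, aic = dev + 2 * d,
       cov = covb, converged = converged, separated = separated)
}

condition_convergence_error <- function(msg, step = NA_integer_) {
  structure(class = c("mivarsel_convergence_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), step = step))
}
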