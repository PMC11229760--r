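#' L2-penalized negative log-likelihood of a logistic model
#'
#' The criterion PELORA minimizes: the Bernoulli negative log-likelihood
#' plus `lambda` times the squared L2 norm of the slopes; the intercept is
#' not penalized. Fitted probabilities are clipped to `[1e-12, 1 - 1e-12]`
#' before taking logs.
#'
#' @param y 0/1 response.
#' @param X design matrix whose first column is the constant 1 (intercept).
#' @param beta coefficient vector (intercept first).
#' @param lambda ridge penalty, `>= 0`.
#' @return the criterion value (scalar).
#' @export
penalized_nll <- function(y, X, beta, lambda) {
  stopifnot(lambda >= 0, ncol(X) == length(beta))
  eta <- drop(X %*% beta)
  p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(beta[-1L]^2)
}

#' Ridge-penalized logistic regression by Newton / IRLS
#'
#' Minimizes [penalized_nll()] by damped Newton iterations (step halving on
#' any criterion increase) until the gradient norm falls below `tol`.
#'
#' @param X design matrix, first column the intercept's constant 1.
#' @param y 0/1 response.
#' @param lambda ridge penalty on the slopes, `>= 0`.
#' @param tol convergence threshold on the gradient's Euclidean norm.
#' @param max_iter iteration cap; exceeding it is an error (with trace).
#' @return list with `coefficients`, `criterion` (the minimized
#'   [penalized_nll()]), `iterations`, `gradient_norm`.
#' @export
fit_ridge_logistic <- function(X, y, lambda, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), lambda >= 0,
            all(X[, 1L] == 1))
  k <- ncol(X)
  pen <- diag(c(0, rep(2 * lambda, k - 1L)), k)   # d2/dbeta2 of lambda*sum(beta_j^2)
  beta <- numeric(k)
  crit <- penalized_nll(y, X, beta, lambda)
  trace <- crit
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, p - y)) + c(0, 2 * lambda * beta[-1L])
    gn <- sqrt(sum(grad^2))
    if (gn < tol)
      return(list(coefficients = beta, criterion = crit,
                  iterations = it - 1L, gradient_norm = gn))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, k), grad))
    # damped update: halve until the criterion does not increase
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      cc <- penalized_nll(y, X, cand, lambda)
      if (cc <= crit + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- cand; crit <- cc; trace <- c(trace, crit)
  }
  p <- stats::plogis(drop(X %*% beta))
  grad <- drop(crossprod(X, p - y)) + c(0, 2 * lambda * beta[-1L])
  if (sqrt(sum(grad^2)) < tol)
    return(list(coefficients = beta, criterion = crit,
                iterations = max_iter, gradient_norm = sqrt(sum(grad^2))))
  stop("ridge logistic fit did not converge in ", max_iter,
       " iterations; criterion trace: ",
       paste(signif(trace, 6), collapse = ", "))
}
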