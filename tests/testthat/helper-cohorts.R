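# fixtures are built in code; nothing is read from disk except inst/extdata

# small deterministic percent table: rows sum to 100
tiny_table <- function() {
  v <- matrix(c(60, 30, 5, 5,
                30, 50, 10, 10,
                20, 20, 30, 30,
                10, 60, 25, 5,
                55, 25, 0, 20,
                40, 40, 15, 5),
              nrow = 6, byrow = TRUE,
              dimnames = list(paste0("S", 1:6), paste0("tax", 1:4)))
  abundance_table(v, c(0, 0, 0, 1, 1, 1), rank = "genus")
}

# random closed composition with optional zeros, both groups
random_table <- function(n = 20, p = 10, seed = 1, zero_frac = 0.1,
                         rank = "species") {
  set.seed(seed)
  l <- matrix(rnorm(n * p, -2, 2), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("t%02d", 1:p)))
  v <- 100 * exp(l) / rowSums(exp(l))
  if (zero_frac > 0) {
    thr <- quantile(v, zero_frac)
    v[v < thr] <- 0
  }
  abundance_table(v, rep(c(0, 1), length.out = n),
                  rank = rank, sum_tolerance = 100)
}

# independent ridge-logistic criterion + fit used as oracle (optim-based,
# shares no code with the package's IRLS)
oracle_pnll <- function(y, X, beta, lambda) {
  eta <- drop(X %*% beta)
  p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(beta[-1]^2)
}

oracle_ridge_fit <- function(X, y, lambda) {
  o <- optim(rep(0, ncol(X)), function(b) oracle_pnll(y, X, b, lambda),
             method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  list(coefficients = o$par, criterion = o$value)
}

# central-difference numeric gradient
numDeriv_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# exhaustive step-by-step forward search for the first PELORA cluster,
# built on the optim oracle
oracle_forward_search <- function(Z, y, lambda, tol = 1e-6) {
  n <- nrow(Z)
  base <- oracle_ridge_fit(matrix(1, n, 1), y, lambda)
  crit <- base$criterion
  members <- character(0)
  sumcol <- numeric(n)
  repeat {
    cand <- setdiff(colnames(Z), members)
    if (!length(cand)) break
    crits <- vapply(cand, function(j) {
      cent <- (sumcol + Z[, j]) / (length(members) + 1)
      oracle_ridge_fit(cbind(1, cent), y, lambda)$criterion
    }, numeric(1))
    if (min(crits) >= crit - tol) break
    j <- cand[which.min(crits)]
    members <- c(members, j)
    sumcol <- sumcol + Z[, j]
    crit <- min(crits)
  }
  members
}
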