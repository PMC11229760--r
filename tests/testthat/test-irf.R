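sim_xy <- function(n = 80, p = 10, seed = 1, informative = 2, beta = 1.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(beta * rowSums(X[, seq_len(informative), drop = FALSE])))
  while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
  list(X = X, y = y)
}

test_that("one iteration is an ordinary uniformly-weighted forest", {
  d <- sim_xy(seed = 2)
  fit <- suppressWarnings(irf(d$X, d$y, K = 1, n_trees = 100, seed = 9,
                              n_boot_ci = 0))
  ref <- ranger::ranger(x = d$X, y = factor(d$y, 0:1), num.trees = 100,
                        mtry = ceiling(sqrt(ncol(d$X))),
                        split.select.weights = rep(1 / ncol(d$X), ncol(d$X)),
                        importance = "impurity", keep.inbag = TRUE,
                        seed = 9, num.threads = 1, verbose = FALSE)
  expect_equal(fit$vimp_raw, ref$variable.importance)
  expect_equal(unname(fit$weight_history[1, ]), rep(1 / 10, 10))
})

test_that("iteration-2 weights are the normalized Gini importances of forest 1", {
  d <- sim_xy(seed = 3)
  fit <- suppressWarnings(irf(d$X, d$y, K = 2, n_trees = 100, seed = 4,
                              n_boot_ci = 0))
  ref <- ranger::ranger(x = d$X, y = factor(d$y, 0:1), num.trees = 100,
                        mtry = ceiling(sqrt(ncol(d$X))),
                        split.select.weights = rep(1 / ncol(d$X), ncol(d$X)),
                        importance = "impurity", keep.inbag = TRUE,
                        seed = 4, num.threads = 1, verbose = FALSE)
  imp <- pmax(ref$variable.importance, 0)
  expect_equal(unname(fit$weight_history[2, ]), unname(imp / sum(imp)),
               tolerance = 1e-12)
  # every weight vector sums to 1
  expect_equal(unname(rowSums(fit$weight_history)), rep(1, 2),
               tolerance = 1e-12)
})

test_that("identical seeds give identical forests, probabilities and AUC", {
  d <- sim_xy(seed = 5)
  f1 <- suppressWarnings(irf(d$X, d$y, K = 3, n_trees = 80, seed = 11,
                             n_boot_ci = 50))
  f2 <- suppressWarnings(irf(d$X, d$y, K = 3, n_trees = 80, seed = 11,
                             n_boot_ci = 50))
  expect_identical(f1$weight_history, f2$weight_history)
  expect_identical(f1$oob_probabilities, f2$oob_probabilities)
  expect_identical(f1$auc, f2$auc)
  expect_true(all(f1$oob_probabilities >= 0 & f1$oob_probabilities <= 1,
                  na.rm = TRUE))
})

test_that("reweighting concentrates on planted informative features", {
  share <- function(K, s) {
    d <- sim_xy(n = 120, p = 20, seed = s, informative = 2, beta = 1.2)
    fit <- suppressWarnings(irf(d$X, d$y, K = K, n_trees = 120, seed = s,
                                n_boot_ci = 0))
    sum(fit$weight_history[K, 1:2])
  }
  gain <- vapply(1:5, function(s) share(5, s) - share(1, s), numeric(1))
  expect_gt(mean(gain), 0)
})

test_that("iteration tuning stays on the published 1..100 range", {
  d <- sim_xy(seed = 6)
  res <- suppressWarnings(tune_iterations(d$X, d$y, K_grid = 3, n_trees = 60,
                                          seed = 2))
  expect_equal(res$K, 3L)
  expect_error(tune_iterations(d$X, d$y, K_grid = c(1, 101), n_trees = 60),
               "1..100")
  res2 <- suppressWarnings(tune_iterations(d$X, d$y, K_grid = c(1, 3),
                                           n_trees = 60, seed = 2))
  expect_true(res2$K %in% c(1L, 3L))
  expect_length(res2$auc, 2L)
})

test_that("AUC follows the rank formulation with a stratified bootstrap CI", {
  # perfectly ranked
  expect_equal(roc_auc(c(.1, .2, .8, .9), c(0, 0, 1, 1), n_boot_ci = 0)[["auc"]], 1)
  # hand case: concordant pairs 3 of 4
  expect_equal(roc_auc(c(.9, .8, .4, .2), c(1, 0, 1, 0), n_boot_ci = 0)[["auc"]],
               0.75)
  # ties count one half (constant probabilities also warn)
  expect_warning(
    tied <- roc_auc(c(.5, .5, .5, .5), c(0, 1, 0, 1), n_boot_ci = 0),
    "constant")
  expect_equal(tied[["auc"]], 0.5)
  # the 1000-replicate stratified CI brackets the point estimate
  set.seed(1)
  probs <- c(rnorm(20, .4, .2), rnorm(20, .6, .2))
  y <- rep(c(0, 1), each = 20)
  res <- roc_auc(probs, y, n_boot_ci = 1000, seed = 3)
  expect_lte(res[["ci_lo"]], res[["auc"]])
  expect_gte(res[["ci_hi"]], res[["auc"]])
  # independent oracle: pROC agrees on the point estimate
  skip_if_not_installed("pROC")
  expect_equal(res[["auc"]],
               as.numeric(pROC::auc(pROC::roc(y, probs, quiet = TRUE))))
})

test_that("missing OOB probabilities are excluded with a warning", {
  expect_warning(res <- roc_auc(c(NA, .2, .8, .9), c(0, 0, 1, 1),
                                n_boot_ci = 0),
                 "missing")
  expect_equal(res[["auc"]], 1)
})

test_that("relative VIMP rescales to percent of the maximum", {
  v <- c(a = 0.02, b = 0.01, c = 0.005)
  expect_equal(unname(relative_vimp(v)), c(100, 50, 25), ignore_attr = TRUE)
  # ordering preserved, maximum exactly 100
  set.seed(7)
  raw <- runif(12)
  rel <- relative_vimp(raw)
  expect_equal(order(rel), order(raw))
  expect_equal(max(rel), 100)
  # non-positive entries flagged, all-non-positive rejected
  flagged <- relative_vimp(c(0.5, -0.1, 0))
  expect_equal(unname(attr(flagged, "excluded")), c(FALSE, TRUE, TRUE))
  expect_error(relative_vimp(c(-1, 0)), "positive")
})
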