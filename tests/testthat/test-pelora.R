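make_z <- function(n, p, seed, signal = 2) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("t%02d", 1:p)))
  Z <- scale(Z)
  y <- rbinom(n, 1, plogis(signal * rowMeans(Z[, 1:2])))
  while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
  z <- structure(list(values = Z, feature_means = colMeans(Z) * 0,
                      feature_sds = rep(1, p), dropped_features = numeric(0),
                      replacement_value = NA_real_,
                      group = setNames(as.integer(y), rownames(Z)),
                      rank = "genus"),
                 class = "zscore_matrix")
  z
}

test_that("the first added taxon is the single-feature criterion minimizer", {
  for (s in 1:5) {
    z <- make_z(40, 8, seed = s)
    lambda <- 0.5
    fit <- pelora(z, lambda = lambda, max_clusters = 1)
    crits <- vapply(colnames(z$values), function(j)
      oracle_ridge_fit(cbind(1, z$values[, j]), z$group, lambda)$criterion,
      numeric(1))
    expect_equal(fit$clusters[[1]][1], names(which.min(crits)))
  }
})

test_that("greedy growth of cluster 1 equals exhaustive forward search", {
  for (s in 1:3) {
    z <- make_z(40, 6, seed = 100 + s)
    fit <- pelora(z, lambda = 1, max_clusters = 1)
    oracle <- oracle_forward_search(z$values, z$group, lambda = 1)
    expect_equal(fit$clusters[[1]], oracle)
  }
})

test_that("criterion trace is non-increasing and clusters stay disjoint", {
  z <- make_z(50, 12, seed = 42)
  fit <- pelora(z, lambda = 0.5, max_clusters = 2)
  for (tr in fit$criterion_trace)
    expect_true(all(diff(tr) <= 0))
  # additions always decrease the running criterion across clusters too
  all_members <- unlist(fit$clusters)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_lte(length(fit$clusters), 2L)
  # degenerate labels rejected
  expect_error(pelora(z, y = rep(1, 50), lambda = 1), "both classes")
})

test_that("with a generous cap the cluster count never exceeds it", {
  z <- make_z(40, 10, seed = 77)
  fit1 <- pelora(z, lambda = 1, max_clusters = 1)
  expect_length(fit1$clusters, 1L)
  fit3 <- pelora(z, lambda = 1, max_clusters = 3)
  expect_lte(length(fit3$clusters), 3L)
})

test_that("a planted cluster shift is recovered in cluster 1", {
  spec <- simulation_spec(n_per_group = c(30, 30), n_taxa = c(species = 45),
                          planted_cluster = list(rank = "species",
                                                 taxa = 1:5, delta = 1.5),
                          seed = 11)
  co <- simulate_cohort(spec)
  z <- transform_abundance(co$tables$species)
  fit <- pelora(z, lambda = 1)
  sc <- score_recovery(fit$clusters[[1]], co$truth$cluster)
  expect_gte(sc$overlap, 0.6)
})

test_that("prediction uses frozen memberships and refit coefficients", {
  z <- make_z(40, 8, seed = 9)
  fit <- pelora(z, lambda = 1)
  p_train <- predict(fit)
  p_new <- predict(fit, newdata = z$values)
  expect_equal(p_train, p_new, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(p_train >= 0 & p_train <= 1))
  expect_equal(residuals(fit), fit$y - p_train, ignore_attr = TRUE)
})

test_that("penalty tuning picks the best median rate, largest lambda on ties", {
  # separable data: tiny penalties all reach 0 OOB misclassification,
  # so the tie must resolve to the largest grid value
  set.seed(21)
  n <- 40
  Z <- scale(matrix(rnorm(n * 4), n, 4))
  colnames(Z) <- paste0("t", 1:4)
  y <- as.integer(Z[, 1] > 0)            # perfectly separable on t1
  z <- structure(list(values = Z, feature_means = rep(0, 4),
                      feature_sds = rep(1, 4), dropped_features = numeric(0),
                      replacement_value = NA_real_,
                      group = setNames(y, rownames(Z)), rank = "genus"),
                 class = "zscore_matrix")
  search <- tune_penalty(z, lambda_grid = c(0.001, 0.01), n_boot = 10,
                         max_clusters = 1, seed = 2)
  expect_equal(unname(search$median_rates), c(0, 0))
  expect_equal(search$lambda, 0.01)
  # single-element grid: that lambda is chosen
  s1 <- tune_penalty(z, lambda_grid = 0.5, n_boot = 3, max_clusters = 1,
                     seed = 3)
  expect_equal(s1$lambda, 0.5)
})

test_that("summary reports member tables in the published layout", {
  z <- make_z(40, 6, seed = 13)
  fit <- pelora(z, lambda = 1)
  sm <- summary(fit)
  tb <- sm$clusters[[1]]$member_table
  expect_true(all(c("taxon", "mean0", "sd0", "mean1", "sd1", "p_value",
                    "test") %in% names(tb)))
  expect_equal(nrow(tb), length(fit$clusters[[1]]))
  # centroid group means agree with the linearity rule
  expect_equal(unname(sm$clusters[[1]]$centroid$group_means["1"]),
               mean(tb$mean1), tolerance = 1e-12)
})
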