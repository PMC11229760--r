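test_that("zero replacement uses half the dataset-wide minimum nonzero percent", {
  v <- rbind(c(99.9998, 0, 0.0002),
             c(99.0, 0.5, 0.5))
  dimnames(v) <- list(c("S1", "S2"), c("a", "b", "c"))
  tab <- abundance_table(v, c(0, 1), "species")
  out <- replace_zeros(tab)
  expect_equal(out$values["S1", "b"], 0.0001)
  expect_equal(attr(out, "replacement_value"), 0.0001)
  # nonzero entries untouched
  expect_equal(out$values[v > 0], v[v > 0])
  # no zeros -> unchanged, replacement NA
  tab2 <- tiny_table()
  tab2$values[tab2$values == 0] <- 1   # remove the one zero
  out2 <- replace_zeros(tab2)
  expect_equal(out2$values, tab2$values)
  expect_true(is.na(attr(out2, "replacement_value")))
  # all-zero matrix is an error
  v0 <- matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("a", "b")))
  expect_error(replace_zeros(abundance_table(v0, c(0, 1), "genus",
                                             sum_tolerance = 200)),
               "all-zero")
})

test_that("new matrix minimum is half the old nonzero minimum whenever zeros existed", {
  for (s in 1:5) {
    tab <- random_table(n = 15, p = 8, seed = s, zero_frac = 0.15)
    old_min <- min(tab$values[tab$values > 0])
    out <- replace_zeros(tab)
    expect_equal(min(out$values), old_min / 2)
  }
})

test_that("logit/Z transform standardizes retained columns and drops constants", {
  tab <- random_table(n = 20, p = 10, seed = 2, zero_frac = 0.1)
  # make one feature identically zero -> constant after replacement
  tab$values[, "t03"] <- 0
  z <- transform_abundance(tab)
  expect_false("t03" %in% colnames(z$values))
  expect_true("t03" %in% names(z$dropped_features))
  # the recorded constant is the logit of the replacement value
  expect_equal(unname(z$dropped_features["t03"]),
               qlogis(z$replacement_value / 100))
  # recompute oracle: every retained column has mean 0, sample SD 1
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-9)
  # stored transform parameters reproduce the logit matrix
  L <- logit_values(z)
  repl <- replace_zeros(tab)
  expect_equal(L, qlogis(repl$values[, colnames(L)] / 100), tolerance = 1e-12)
})

test_that("a 50% abundance has logit zero before standardization", {
  v <- rbind(c(50, 30, 20), c(50, 10, 40), c(50, 25, 25), c(50, 45, 5))
  dimnames(v) <- list(paste0("S", 1:4), c("half", "x", "y"))
  z <- transform_abundance(abundance_table(v, c(0, 0, 1, 1), "genus"))
  # 'half' is constant at logit(0.5) = 0
  expect_equal(unname(z$dropped_features["half"]), 0)
  expect_error(logit_zscore(abundance_table(v, c(0, 0, 1, 1), "genus") |>
                              (\(t) { t$values[1, 1] <- 100; t })()),
               "strictly")
})

test_that("logit transform is strictly monotone within each feature", {
  tab <- random_table(n = 25, p = 6, seed = 9, zero_frac = 0.2)
  z <- transform_abundance(tab)
  repl <- replace_zeros(tab)
  for (j in colnames(z$values))
    expect_equal(order(z$values[, j]), order(repl$values[, j]))
})

test_that("standardization is idempotent", {
  tab <- random_table(n = 18, p = 5, seed = 4, zero_frac = 0)
  z <- transform_abundance(tab)
  restd <- scale(z$values)
  expect_lt(max(abs(restd - z$values)), 1e-9)
})

test_that("centroid is the per-sample mean of member Z-scores and is linear", {
  tab <- random_table(n = 16, p = 8, seed = 5, zero_frac = 0.1)
  z <- transform_abundance(tab)
  members <- colnames(z$values)[1:3]
  ce <- centroid(z, members)
  expect_equal(ce$values, rowMeans(z$values[, members]), tolerance = 1e-12)
  # single-member cluster equals that column
  c1 <- centroid(z, members[1])
  expect_equal(c1$values, z$values[, members[1]], tolerance = 1e-15)
  # linearity: group mean of centroid = mean of member group means
  g <- z$group
  for (gr in 0:1) {
    member_means <- colMeans(z$values[g == gr, members])
    expect_equal(unname(ce$group_means[as.character(gr)]),
                 mean(member_means), tolerance = 1e-12)
  }
  expect_error(centroid(z, "nonexistent_taxon"), "unknown")
})

test_that("group comparison: Welch t by default, Mann-Whitney on zero variance", {
  # identical distributions -> t = 0, p = 1
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1)
  res <- compare_groups(x, g)
  expect_equal(res$test_used, "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand Welch formula on (1,2,3) vs (4,5,6): t = -3 / sqrt(2/3)
  res2 <- compare_groups(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(res2$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  # zero variance in one group -> Mann-Whitney
  res3 <- compare_groups(c(5, 5, 5, 1, 2, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(res3$test_used, "mann-whitney")
  expect_error(compare_groups(c(1, 2, 3), c(0, 1, 1)), "at least 2")
})

test_that("absent-in-one-group members get the pooled-standardization constant", {
  # pooled mean zero: n0 * c + n1 * m1 = 0
  expect_equal(impute_absent_z(25, 28, 0.168), -28 * 0.168 / 25)
  expect_equal(impute_absent_z(2, 2, 0.5), -0.5)
  cm <- centroid_group_means(mean0 = c(0.4, NA), mean1 = c(-0.2, 0.3),
                             n = c(10, 10))
  expect_equal(unname(cm["0"]), mean(c(0.4, -0.3)))
  expect_equal(unname(cm["1"]), mean(c(-0.2, 0.3)))
  expect_error(centroid_group_means(NA, NA), "at least one group")
})
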