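# independent path extractor built on treeInfo(), used as the oracle for
# leaf_itemsets()'s direct walk of the forest arrays
treeinfo_itemsets <- function(fit, X) {
  term <- predict(fit, data = X, type = "terminalNodes",
                  num.threads = 1)$predictions
  itemsets <- list(); weights <- numeric(0)
  for (t in seq_len(fit$num.trees)) {
    ti <- ranger::treeInfo(fit, t)
    if (nrow(ti) == 1) next
    paths <- list("0" = integer(0))
    for (i in seq_len(nrow(ti))) {
      if (ti$terminal[i]) next
      f <- union(paths[[as.character(ti$nodeID[i])]],
                 ti$splitvarID[i] + 1L)
      paths[[as.character(ti$leftChild[i])]] <- f
      paths[[as.character(ti$rightChild[i])]] <- f
    }
    leaves <- ti$nodeID[ti$terminal & ti$prediction == "1"]
    cnt <- table(factor(term[, t], levels = ti$nodeID))
    for (nd in leaves) {
      s <- sort(paths[[as.character(nd)]])
      if (!length(s)) next
      itemsets <- c(itemsets, list(s))
      weights <- c(weights, as.numeric(cnt[as.character(nd)]))
    }
  }
  list(itemsets = itemsets, weights = weights)
}

test_that("leaf itemsets match an independent treeInfo-based extraction", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(as.integer(X[, 1] + X[, 2] > 0), 0:1)
  fit <- ranger::ranger(x = X, y = y, num.trees = 15, seed = 3,
                        num.threads = 1, keep.inbag = TRUE, verbose = FALSE)
  got <- leaf_itemsets(fit, X)
  ref <- treeinfo_itemsets(fit, X)
  key <- function(li) sort(paste(vapply(li$itemsets, paste, character(1),
                                        collapse = ","), li$weights))
  expect_equal(key(got), key(ref))
  expect_true(all(got$weights >= 0))
  expect_equal(got$feature_names, colnames(X))
})

test_that("intersection trees recover prevalent itemsets and reject chance ones", {
  set.seed(2)
  # every itemset contains {1,2}: the pair must survive
  its <- replicate(50, sort(c(1L, 2L, sample(3:10, 3))), simplify = FALSE)
  out <- random_intersection_trees(its, depth = 5, branch = 2, n_trees = 100)
  expect_true(any(vapply(out, function(s) identical(s, c(1L, 2L)), logical(1))))
  # disjoint singletons: nothing of order >= 2 can survive
  its2 <- lapply(1:20, function(i) i)
  out2 <- random_intersection_trees(its2, depth = 3, branch = 2, n_trees = 50)
  expect_length(out2, 0)
  # the support filter drops one-off chance intersections
  set.seed(3)
  rare <- c(replicate(97, sort(sample(1:40, 4)), simplify = FALSE),
            replicate(3, c(1L, 2L), simplify = FALSE))
  loose <- random_intersection_trees(rare, depth = 2, branch = 2,
                                     n_trees = 400, min_tree_fraction = 0)
  strict <- random_intersection_trees(rare, depth = 2, branch = 2,
                                      n_trees = 400, min_tree_fraction = 0.1)
  expect_gt(length(loose), length(strict))
})

test_that("mined interactions carry valid stabilities and are reproducible", {
  spec <- simulation_spec(n_per_group = c(50, 50), n_taxa = c(genus = 12),
                          planted_interaction = list(rank = "genus",
                                                     features = c(1, 2)),
                          seed = 21)
  co <- simulate_cohort(spec)
  z <- transform_abundance(co$tables$genus)
  L <- logit_values(z)
  mi <- mine_interactions(L, z$group, K = 2, n_boot = 6, n_trees = 80,
                          n_rit_trees = 80, seed = 5)
  expect_s3_class(mi, "interaction_stability")
  expect_true(all(mi$stability >= 0 & mi$stability <= 1))
  expect_true(all(mi$order >= 2))
  expect_true(!is.unsorted(rev(mi$stability)))
  mi2 <- mine_interactions(L, z$group, K = 2, n_boot = 6, n_trees = 80,
                           n_rit_trees = 80, seed = 5)
  expect_identical(mi, mi2)
})

test_that("edge lists keep only pairwise interactions above threshold", {
  df <- data.frame(interaction = c("a : b", "a : b : c", "c : d"),
                   order = c(2L, 3L, 2L), stability = c(0.9, 0.8, 0.3))
  attr(df, "sets") <- list(c("a", "b"), c("a", "b", "c"), c("c", "d"))
  class(df) <- c("interaction_stability", "data.frame")
  ed <- interaction_edges(df, threshold = 0.5)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$from, "a")
  expect_equal(ed$to, "b")
  ed2 <- interaction_edges(df, threshold = 0.95)
  expect_equal(nrow(ed2), 0L)
})
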