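#' Class-1 decision-path itemsets of a forest
#'
#' Maps a fitted forest to binary interaction data: for every leaf whose
#' predicted class is 1, the set of distinct features tested on the
#' root-to-leaf path forms an itemset, weighted by the number of training
#' samples falling into that leaf. These itemsets are the input of the
#' generalized Random Intersection Trees miner ([random_intersection_trees()]).
#'
#' @param fit a \pkg{ranger} classification fit (trained with the 0/1
#'   factor convention used throughout this package).
#' @param X the training feature matrix (used to count samples per leaf).
#' @return list with `itemsets` (list of integer vectors of feature
#'   indices), `weights` (numeric leaf sample counts), `feature_names`.
#' @export
leaf_itemsets <- function(fit, X) {
  forest <- fit$forest
  code1 <- forest$class.values[match("1", forest$levels)]
  term <- stats::predict(fit, data = X, type = "terminalNodes",
                         num.threads = 1L)$predictions
  itemsets <- list(); weights <- numeric(0)
  for (t in seq_len(forest$num.trees)) {
    left <- forest$child.nodeIDs[[t]][[1]]
    right <- forest$child.nodeIDs[[t]][[2]]
    varid <- forest$split.varIDs[[t]]      # 0-based
    vals <- forest$split.values[[t]]
    n_nodes <- length(left)
    if (n_nodes == 1L) next                # single-leaf tree: empty path
    is_term <- left == 0 & right == 0
    # accumulate path feature sets; children always follow their parent
    feats <- vector("list", n_nodes)
    feats[[1]] <- integer(0)
    for (nd in which(!is_term)) {
      f <- union(feats[[nd]], varid[nd] + 1L)
      feats[[left[nd] + 1L]] <- f
      feats[[right[nd] + 1L]] <- f
    }
    leaves <- which(is_term & vals == code1)
    if (!length(leaves)) next
    cnt <- tabulate(term[, t] + 1L, nbins = n_nodes)
    keep <- leaves[lengths(feats[leaves]) > 0L]
    itemsets <- c(itemsets, lapply(feats[keep], sort))
    weights <- c(weights, cnt[keep])
  }
  list(itemsets = itemsets, weights = weights,
       feature_names = forest$independent.variable.names)
}

#' Generalized Random Intersection Trees
#'
#' Mines feature sets prevalent among weighted itemsets: each of
#' `n_trees` intersection trees draws a root itemset (with probability
#' proportional to its weight) and recursively intersects it with freshly
#' drawn itemsets along `branch` children per node down to depth `depth`;
#' the surviving depth-`depth` intersections of order >= 2 are returned.
#'
#' @param itemsets list of integer vectors (e.g. from [leaf_itemsets()]).
#' @param weights sampling weights, one per itemset.
#' @param depth tree depth (number of intersection rounds).
#' @param branch children per node.
#' @param n_trees number of intersection trees.
#' @param min_order smallest itemset order kept.
#' @param min_tree_fraction support filter: an itemset is reported only if
#'   at least this fraction of the intersection trees emit it (0 keeps
#'   every survivor). Itemsets prevalent among the input survive many
#'   trees; chance intersections survive isolated ones, so a small support
#'   requirement separates the two.
#' @return list of unique sorted integer vectors (the mined interactions),
#'   with attribute `tree_counts` (number of emitting trees per itemset).
#' @export
random_intersection_trees <- function(itemsets, weights = NULL, depth = 5L,
                                      branch = 2L, n_trees = 500L,
                                      min_order = 2L, min_tree_fraction = 0) {
  m <- length(itemsets)
  if (m == 0L) return(list())
  if (is.null(weights)) weights <- rep(1, m)
  prob <- weights / sum(weights)
  found <- new.env(hash = TRUE, parent = emptyenv())
  counts <- new.env(hash = TRUE, parent = emptyenv())
  draws_per_tree <- sum(branch^(seq_len(depth) - 1L)) * branch  # upper bound
  for (tr in seq_len(n_trees)) {
    pool <- sample.int(m, draws_per_tree + 1L, replace = TRUE, prob = prob)
    pos <- 1L
    nodes <- list(itemsets[[pool[pos]]])
    emitted <- character(0)
    for (d in seq_len(depth)) {
      nxt <- list()
      for (s in nodes) {
        for (b in seq_len(branch)) {
          pos <- pos + 1L
          child <- intersect(s, itemsets[[pool[pos]]])
          if (length(child) >= min_order) nxt[[length(nxt) + 1L]] <- child
        }
      }
      if (!length(nxt)) break
      nodes <- nxt
      if (d == depth)
        for (s in nodes) {
          key <- paste(s, collapse = "_")
          if (!(key %in% emitted)) {
            emitted <- c(emitted, key)
            assign(key, s, envir = found)
            prev <- if (exists(key, envir = counts)) get(key, envir = counts) else 0L
            assign(key, prev + 1L, envir = counts)
          }
        }
    }
  }
  keys <- ls(found)
  ntree <- vapply(keys, function(k) get(k, envir = counts), integer(1))
  keep <- ntree >= min_tree_fraction * n_trees
  out <- unname(lapply(keys[keep], function(k) get(k, envir = found)))
  attr(out, "tree_counts") <- unname(ntree[keep])
  out
}

#' Mine stable taxon-taxon interactions with bootstrapped iRF + RIT
#'
#' For each of `n_boot` outer bootstrap resamples of the cohort: refit the
#' `K`-iteration feature-weighted forest ([irf()]), convert its class-1
#' decision paths to weighted itemsets ([leaf_itemsets()]) and mine
#' prevalent intersections ([random_intersection_trees()]). An
#' interaction's stability score is the fraction of bootstraps in which it
#' is recovered (0 = never, 1 = always). Only interactions of order >= 2
#' are reported, sorted by decreasing stability.
#'
#' @inheritParams irf
#' @param n_boot outer bootstrap resamples (`>= 2`).
#' @param rit_depth,rit_branch,n_rit_trees RIT parameters.
#' @param min_tree_fraction within-bootstrap support filter, passed to
#'   [random_intersection_trees()].
#' @return Object of class `interaction_stability`: data frame with
#'   columns `interaction` (feature names joined by " : "), `order`,
#'   `stability`; the feature-index sets are kept in attribute `sets`.
#' @export
mine_interactions <- function(X, y = NULL, K = 5L, n_boot = 30L,
                              n_trees = 500L, mtry = NULL,
                              rit_depth = 5L, rit_branch = 2L,
                              n_rit_trees = 500L, min_tree_fraction = 0.04,
                              seed = 1L) {
  if (inherits(X, "zscore_matrix")) {
    if (is.null(y)) y <- X$group
    X <- X$values
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- encode_group(y)
  stopifnot(n_boot >= 2L)
  n <- nrow(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max - 200L, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    fb <- irf(X[idx, , drop = FALSE], y[idx], K = K, n_trees = n_trees,
              mtry = mtry, seed = boot_seeds[b], n_boot_ci = 0L)
    li <- leaf_itemsets(fb$forest, X[idx, , drop = FALSE])
    if (!length(li$itemsets)) {
      message("bootstrap ", b, ": forest has no class-1 leaves")
      next
    }
    set.seed(boot_seeds[b] + 1L)
    mined <- random_intersection_trees(li$itemsets, li$weights,
                                       depth = rit_depth, branch = rit_branch,
                                       n_trees = n_rit_trees,
                                       min_tree_fraction = min_tree_fraction)
    for (s in mined) {
      key <- paste(s, collapse = "_")
      prev <- if (exists(key, envir = counts)) get(key, envir = counts) else 0L
      assign(key, prev + 1L, envir = counts)
    }
  }
  keys <- ls(counts)
  sets <- lapply(strsplit(keys, "_", fixed = TRUE), as.integer)
  stab <- vapply(keys, function(k) get(k, envir = counts), integer(1)) / n_boot
  o <- order(-stab, keys)
  res <- data.frame(
    interaction = vapply(sets[o], function(s)
      paste(colnames(X)[s], collapse = " : "), character(1)),
    order = lengths(sets[o]),
    stability = unname(stab[o]),
    stringsAsFactors = FALSE)
  attr(res, "sets") <- lapply(sets[o], function(s) colnames(X)[s])
  class(res) <- c("interaction_stability", "data.frame")
  res
}

#' Edge list of stable pairwise interactions for network rendering
#'
#' @param interactions an `interaction_stability` result.
#' @param threshold minimal stability kept (network convention 0.5).
#' @return data frame `from`, `to`, `stability` (pairwise interactions
#'   only).
#' @export
interaction_edges <- function(interactions, threshold = 0.5) {
  sets <- attr(interactions, "sets")
  keep <- which(interactions$order == 2L & interactions$stability >= threshold)
  if (!length(keep))
    return(data.frame(from = character(0), to = character(0),
                      stability = numeric(0)))
  data.frame(from = vapply(sets[keep], `[`, character(1), 1L),
             to = vapply(sets[keep], `[`, character(1), 2L),
             stability = interactions$stability[keep])
}
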