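#' Iterative Random Forest (iRF)
#'
#' Fits a sequence of feature-weighted random forests: iteration 1 uses
#' uniform split-selection weights; iteration `k + 1` draws each node's
#' split candidates with probability proportional to the Gini importances
#' of iteration `k` (negative importances clipped to 0, weights
#' renormalized to sum 1; if fewer than `mtry` weights remain positive, a
#' 0.1% uniform admixture keeps node sampling feasible). Reweighting concentrates splits on the features
#' that matter, which stabilizes both importance rankings and the decision
#' paths that interaction mining ([mine_interactions()]) consumes. The last
#' forest provides out-of-bag vote-fraction probabilities, relative
#' variable importance ([relative_vimp()]) and an OOB ROC AUC with a
#' stratified-bootstrap confidence interval ([roc_auc()]).
#'
#' Features are expected on the logit scale (e.g. the logit-transformed
#' abundances underlying a `zscore_matrix`); forests are invariant to this
#' monotone transform but interpretation axes then match the transform
#' used throughout the package.
#'
#' @param X numeric feature matrix (samples x features, named columns), or
#'   a `zscore_matrix` (its `values` are used). Clinical covariates may be
#'   appended as extra columns by the caller.
#' @param y 0/1 labels (defaults to `X$group` for a `zscore_matrix`).
#' @param K number of iterations (`>= 1`; `K = 1` is an ordinary random
#'   forest).
#' @param n_trees trees per forest.
#' @param mtry split candidates per node; default `ceiling(sqrt(p))`.
#' @param seed integer seed; iteration `k` uses `seed + k - 1`.
#' @param n_boot_ci stratified bootstrap replicates for the AUC CI.
#' @return Object of class `irf`: list with `forest` (the final
#'   \pkg{ranger} fit), `K`, `weight_history` (K x p, rows sum to 1),
#'   `oob_probabilities` (per sample; `NA` if never out-of-bag),
#'   `vimp_raw`, `vimp_relative` (percent of maximum, positive importances
#'   only), `auc` (with `ci_lo`, `ci_hi`), `y`, `n_trees`, `mtry`, `seed`.
#' @export
irf <- function(X, y = NULL, K = 5L, n_trees = 500L, mtry = NULL,
                seed = 1L, n_boot_ci = 1000L) {
  if (inherits(X, "zscore_matrix")) {
    if (is.null(y)) y <- X$group
    X <- X$values
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- encode_group(y)
  stopifnot(K >= 1L, nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  yf <- factor(y, levels = 0:1)

  w <- rep(1 / p, p)
  weight_history <- matrix(NA_real_, K, p, dimnames = list(NULL, colnames(X)))
  fit <- NULL
  for (k in seq_len(K)) {
    weight_history[k, ] <- w
    fit <- suppressWarnings(ranger::ranger(
      x = X, y = yf, num.trees = n_trees, mtry = mtry,
      split.select.weights = w, importance = "impurity",
      keep.inbag = TRUE, seed = seed + k - 1L, num.threads = 1L,
      verbose = FALSE))
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) == 0) {
      message("all-zero importance vector; weights reset to uniform")
      w <- rep(1 / p, p)
    } else w <- next_weights(imp, mtry)
  }

  oob <- oob_vote_probabilities(fit, X)
  vimp <- fit$variable.importance
  auc <- roc_auc(oob, y, n_boot_ci = n_boot_ci, seed = seed)
  structure(list(forest = fit, K = K, weight_history = weight_history,
                 oob_probabilities = oob,
                 vimp_raw = vimp,
                 vimp_relative = tryCatch(relative_vimp(vimp),
                                          error = function(e) NULL),
                 auc = auc, y = y, n_trees = n_trees, mtry = mtry,
                 seed = seed, call = match.call()),
            class = "irf")
}

# normalized clipped importances; when fewer than mtry are positive a
# minimal uniform admixture keeps every node able to draw mtry candidates
next_weights <- function(imp, mtry) {
  w <- imp / sum(imp)
  if (sum(w > 0) < mtry) w <- 0.999 * w + 0.001 / length(w)
  w
}

# OOB probability of class 1 = fraction of trees not containing the sample
# that vote class 1
oob_vote_probabilities <- function(fit, X) {
  pa <- stats::predict(fit, data = X, predict.all = TRUE,
                       num.threads = 1L)$predictions
  code1 <- fit$forest$class.values[match("1", fit$forest$levels)]
  ib <- simplify2array(fit$inbag.counts)
  oob_mask <- ib == 0
  votes1 <- (pa == code1) * oob_mask
  n_oob <- rowSums(oob_mask)
  prob <- rowSums(votes1) / n_oob
  prob[n_oob == 0] <- NA_real_
  if (anyNA(prob))
    warning(sum(is.na(prob)), " sample(s) never out-of-bag; probability NA")
  names(prob) <- rownames(X)
  prob
}

#' @export
print.irf <- function(x, ...) {
  cat(sprintf("iRF fit: K = %d iterations, %d trees, mtry = %d\n",
              x$K, x$n_trees, x$mtry))
  cat(sprintf("  OOB AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$auc["auc"], x$auc["ci_lo"], x$auc["ci_hi"]))
  top <- utils::head(sort(x$vimp_relative, decreasing = TRUE), 5)
  cat("  top VIMP (%):", paste(sprintf("%s=%.1f", names(top), top),
                               collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.irf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$oob_probabilities)
  if (inherits(newdata, "zscore_matrix")) newdata <- newdata$values
  pr <- stats::predict(object$forest, data = as.matrix(newdata),
                       predict.all = TRUE, num.threads = 1L)$predictions
  code1 <- object$forest$forest$class.values[match("1", object$forest$forest$levels)]
  rowMeans(pr == code1)
}

#' Barplot of relative variable importance
#' @param x an [irf()] fit.
#' @param top number of features shown.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.irf <- function(x, top = 20L, ...) {
  v <- sort(x$vimp_relative, decreasing = TRUE)
  v <- utils::head(v, top)
  graphics::barplot(rev(v), horiz = TRUE, las = 1,
                    xlab = "relative VIMP (%)", ...)
  invisible(x)
}

#' Choose the iteration count by out-of-bag AUC
#'
#' Runs the iterative reweighting once up to `max(K_grid)` and scores the
#' OOB AUC of the forest at every grid value; the AUC-maximizing `K` is
#' chosen, ties broken toward the smallest `K`. Grid values must lie in
#' 1..100.
#'
#' @inheritParams irf
#' @param K_grid candidate iteration counts.
#' @return list with `K` (chosen), `auc` (named per grid value).
#' @export
tune_iterations <- function(X, y = NULL, K_grid = c(1L, 5L, 10L),
                            n_trees = 500L, mtry = NULL, seed = 1L) {
  if (inherits(X, "zscore_matrix")) {
    if (is.null(y)) y <- X$group
    X <- X$values
  }
  K_grid <- sort(unique(as.integer(K_grid)))
  stopifnot(length(K_grid) >= 1L)
  if (any(K_grid < 1L | K_grid > 100L)) stop("K_grid values must lie in 1..100")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- encode_group(y)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  yf <- factor(y, levels = 0:1)

  w <- rep(1 / p, p)
  aucs <- stats::setNames(numeric(length(K_grid)), K_grid)
  for (k in seq_len(max(K_grid))) {
    fit <- suppressWarnings(ranger::ranger(
      x = X, y = yf, num.trees = n_trees, mtry = mtry,
      split.select.weights = w, importance = "impurity",
      keep.inbag = TRUE, seed = seed + k - 1L, num.threads = 1L,
      verbose = FALSE))
    imp <- pmax(fit$variable.importance, 0)
    w <- if (sum(imp) == 0) rep(1 / p, p) else next_weights(imp, mtry)
    if (k %in% K_grid) {
      oob <- suppressWarnings(oob_vote_probabilities(fit, X))
      aucs[as.character(k)] <-
        suppressWarnings(roc_auc(oob, y, n_boot_ci = 0)[["auc"]])
    }
  }
  K <- K_grid[which.max(aucs)]  # which.max takes the first (smallest K) on ties
  list(K = K, auc = aucs)
}

#' ROC AUC with a stratified-bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation, ties counted 1/2. The
#' confidence interval is the 2.5/97.5 percentile of the AUC over
#' `n_boot_ci` stratified bootstrap replicates (resampling within each
#' class). `NA` probabilities (samples never out-of-bag) are excluded with
#' a warning; constant probabilities give AUC 0.5 with a warning.
#'
#' @param probs predicted probabilities of class 1.
#' @param y 0/1 labels.
#' @param n_boot_ci bootstrap replicates (0 skips the CI).
#' @param seed RNG seed for the resampling.
#' @return named numeric `c(auc=, ci_lo=, ci_hi=)`.
#' @export
roc_auc <- function(probs, y, n_boot_ci = 1000L, seed = 1L) {
  y <- encode_group(y)
  keep <- !is.na(probs)
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " sample(s) with missing probability")
    probs <- probs[keep]; y <- y[keep]
  }
  if (length(unique(y)) < 2L) stop("both classes required")
  point <- auc_rank(probs, y)
  if (stats::sd(probs) == 0) warning("constant probabilities; AUC is 0.5")
  if (n_boot_ci < 1L)
    return(c(auc = point, ci_lo = NA_real_, ci_hi = NA_real_))
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot_ci), function(b) {
    idx <- c(sample(i0, length(i0), replace = TRUE),
             sample(i1, length(i1), replace = TRUE))
    auc_rank(probs[idx], y[idx])
  }, numeric(1))
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  c(auc = point, ci_lo = ci[1], ci_hi = ci[2])
}

auc_rank <- function(probs, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs)                       # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rescale variable importances to percent of the maximum
#'
#' Each importance is multiplied by `100 / max`; the maximum maps to
#' exactly 100. Non-positive entries are kept but flagged (attribute
#' `excluded`), matching the display convention of showing only VIMP > 0.
#'
#' @param importances named numeric vector; at least one entry must be
#'   positive.
#' @return numeric vector on the 0-100 scale with attribute `excluded`
#'   (logical mask of non-positive raw importances).
#' @export
relative_vimp <- function(importances) {
  if (all(importances <= 0)) stop("no positive importance")
  out <- importances * 100 / max(importances)
  attr(out, "excluded") <- importances <= 0
  out
}
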