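#' Accumulated Local Effects curve for one feature
#'
#' First-order ALE on quantile bins: within each bin the local effect is
#' the mean, over the samples it contains, of
#' `f(x with feature at upper edge) - f(x with feature at lower edge)`
#' (only the target feature is moved); local effects are accumulated over
#' the bins and centered so that the count-weighted mean is zero — an ALE
#' of 0 is the average predicted risk, and e.g. +0.30 reads as a predicted
#' probability 30 points above it.
#'
#' @param predict_fn function taking a feature matrix and returning
#'   probabilities (e.g. `function(m) predict(fit, m)` for an [irf()] fit).
#' @param X feature matrix the curve is evaluated on.
#' @param feature column name (or index) of the target feature; needs at
#'   least 2 distinct values.
#' @param n_bins requested number of quantile bins; bins emptied by heavy
#'   ties (e.g. mass at the replaced-zero value) are merged.
#' @return Object of class `ale_curve`: list with `feature`, `edges`
#'   (strictly increasing), `effect` (centered accumulated effect at each
#'   bin's upper edge), `counts` (samples per bin).
#' @export
ale_curve <- function(predict_fn, X, feature, n_bins = 20L) {
  X <- as.matrix(X)
  x <- X[, feature]
  if (length(unique(x)) < 2L) stop("constant feature")
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) stop("could not form bins")
  nb <- length(edges) - 1L
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = nb)
  local <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- which(bin == b)
    if (!length(idx)) next                 # merged-away bin (kept at 0)
    hi <- X[idx, , drop = FALSE]; hi[, feature] <- edges[b + 1L]
    lo <- X[idx, , drop = FALSE]; lo[, feature] <- edges[b]
    local[b] <- mean(predict_fn(hi) - predict_fn(lo))
  }
  acc <- cumsum(local)
  centered <- acc - sum(counts * acc) / sum(counts)
  structure(list(feature = if (is.character(feature)) feature else colnames(X)[feature],
                 edges = edges, effect = centered, counts = counts),
            class = "ale_curve")
}

#' @export
print.ale_curve <- function(x, ...) {
  cat(sprintf("ALE curve for '%s': %d bins, effect range [%.4f, %.4f]\n",
              x$feature, length(x$effect), min(x$effect), max(x$effect)))
  invisible(x)
}

#' @export
plot.ale_curve <- function(x, ...) {
  mid <- (x$edges[-1] + x$edges[-length(x$edges)]) / 2
  graphics::plot(mid, x$effect, type = "b", xlab = x$feature,
                 ylab = "ALE (probability)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Two-feature partial dependence surface
#'
#' Grid at the marginal quantiles of each feature; every cell's value is
#' the mean prediction over all samples with the pair clamped to the
#' cell's values. Cells at or above `risk_threshold` are flagged as the
#' high-risk region.
#'
#' @param predict_fn as in [ale_curve()].
#' @param X feature matrix.
#' @param pair two distinct column names (or indices).
#' @param grid_size points per axis (`>= 2`), placed at marginal quantiles
#'   (duplicates from ties removed).
#' @param risk_threshold probability flagging a cell high-risk.
#' @return Object of class `pdp_surface`: list with `pair`, `grid1`,
#'   `grid2`, `values` (grid1 x grid2 matrix of mean predicted
#'   probabilities), `high_risk` (logical matrix), `risk_threshold`.
#' @export
pdp_surface <- function(predict_fn, X, pair, grid_size = 20L,
                        risk_threshold = 0.5) {
  X <- as.matrix(X)
  stopifnot(length(pair) == 2L, grid_size >= 2L)
  if (is.character(pair) && !all(pair %in% colnames(X)))
    stop("unknown feature in pair")
  if (pair[1] == pair[2]) stop("pair must name two distinct features")
  qs <- seq(0, 1, length.out = grid_size)
  g1 <- unique(stats::quantile(X[, pair[1]], qs, names = FALSE, type = 7))
  g2 <- unique(stats::quantile(X[, pair[2]], qs, names = FALSE, type = 7))
  vals <- matrix(NA_real_, length(g1), length(g2))
  for (i in seq_along(g1)) for (j in seq_along(g2)) {
    Xc <- X
    Xc[, pair[1]] <- g1[i]
    Xc[, pair[2]] <- g2[j]
    vals[i, j] <- mean(predict_fn(Xc))
  }
  structure(list(pair = pair, grid1 = g1, grid2 = g2, values = vals,
                 high_risk = vals >= risk_threshold,
                 risk_threshold = risk_threshold),
            class = "pdp_surface")
}

#' @export
print.pdp_surface <- function(x, ...) {
  cat(sprintf("PDP surface %s x %s: %d x %d grid, %d high-risk cell(s) (>= %.2f)\n",
              x$pair[1], x$pair[2], length(x$grid1), length(x$grid2),
              sum(x$high_risk), x$risk_threshold))
  invisible(x)
}

#' @export
plot.pdp_surface <- function(x, ...) {
  graphics::image(x$grid1, x$grid2, x$values, xlab = x$pair[1],
                  ylab = x$pair[2], ...)
  invisible(x)
}

#' Features eligible for ALE display
#'
#' Pure filter: features whose relative VIMP exceeds `threshold` percent
#' (display convention: 10%).
#'
#' @param fit an [irf()] fit.
#' @param threshold percent of the maximum importance.
#' @return character vector of feature names, most important first.
#' @export
select_ale_features <- function(fit, threshold = 10) {
  v <- fit$vimp_relative
  v <- v[!attr(v, "excluded") & v > threshold]
  names(sort(v, decreasing = TRUE))
}

#' Interaction pairs eligible for PDP display
#'
#' Pure filter: pairwise interactions with stability above `threshold`
#' (display convention: 0.70).
#'
#' @param interactions an `interaction_stability` result
#'   (see [mine_interactions()]).
#' @param threshold stability cutoff (exclusive).
#' @return list of 2-element character vectors.
#' @export
select_pdp_pairs <- function(interactions, threshold = 0.70) {
  sets <- attr(interactions, "sets")
  keep <- which(interactions$order == 2L & interactions$stability > threshold)
  sets[keep]
}
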