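#' PELORA: supervised clustering by penalized logistic regression
#'
#' Greedily grows clusters of taxa whose centroids (per-sample mean
#' Z-scores, see [centroid()]) act as covariates of a ridge-penalized
#' logistic model for the binary group label. Each cluster is grown by
#' adding, at every step, the candidate taxon whose inclusion (recompute
#' the centroid, refit the ridge logistic model on all current centroids)
#' most decreases the L2-penalized negative log-likelihood
#' ([penalized_nll()]); growth stops when no candidate improves the
#' criterion by more than `tol`. A finished cluster's membership is frozen;
#' its centroid stays in the design while later clusters grow, so earlier
#' clusters still shape the next one. At most `max_clusters` clusters are
#' returned (two by default, the interpretability cap used for the
#' pancreatic-cancer cohort analyses this package re-implements).
#'
#' @param z a `zscore_matrix` from [logit_zscore()] /
#'   [transform_abundance()].
#' @param y 0/1 labels (defaults to `z$group`); both classes required.
#' @param lambda ridge penalty `>= 0` applied to the centroid slopes.
#' @param max_clusters cluster cap.
#' @param tol minimal criterion decrease for an addition to be kept.
#' @param sign_flip if `TRUE`, a candidate may also enter a centroid
#'   negated (as `-Z`), whichever direction fits better. Off by default:
#'   published centroids of this analysis are plain means.
#' @param fixed_covariates optional numeric matrix of extra unpenalized-in-
#'   spirit covariates (e.g. clinical variables) kept in the design
#'   throughout; their slopes are penalized like the centroid slopes.
#' @return An object of class `pelora`: list with `clusters` (list of
#'   member-taxon character vectors, in growth order), `signs` (parallel
#'   list of +1/-1 entry signs), `lambda`, `coefficients` (intercept then
#'   one slope per fixed covariate and per cluster centroid),
#'   `criterion_trace` (list, per cluster, of criterion values after each
#'   addition), `centroids` (samples x clusters), `y`, `z`.
#' @seealso [tune_penalty()] to choose `lambda`, [summary.pelora()] for a
#'   per-cluster membership report.
#' @export
pelora <- function(z, y = z$group, lambda = 1, max_clusters = 2L,
                   tol = 1e-6, sign_flip = FALSE, fixed_covariates = NULL) {
  stopifnot(inherits(z, "zscore_matrix"), lambda >= 0, max_clusters >= 1L)
  y <- as.numeric(encode_group(y))
  Z <- z$values
  n <- nrow(Z)
  if (length(y) != n) stop("label length mismatch")
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (ncol(Z) < 1L) stop("no retained features to cluster")

  fixed <- if (is.null(fixed_covariates)) NULL else as.matrix(fixed_covariates)
  design <- function(cent_cols) {
    cbind(rep(1, n), fixed, cent_cols, deparse.level = 0)
  }

  clusters <- list(); signs <- list(); traces <- list()
  cent_done <- NULL                      # frozen centroids of finished clusters
  used <- character(0)
  base_fit <- fit_ridge_logistic(design(cent_done), y, lambda)
  criterion <- base_fit$criterion
  final_fit <- base_fit

  for (k in seq_len(max_clusters)) {
    cand <- setdiff(colnames(Z), used)
    members <- character(0); msign <- numeric(0)
    sumcol <- numeric(n)                  # running sum of signed member columns
    trace <- numeric(0)
    repeat {
      if (!length(cand)) break
      best <- NULL
      for (j in cand) {
        for (s in if (sign_flip) c(1, -1) else 1) {
          cent_new <- (sumcol + s * Z[, j]) / (length(members) + 1L)
          ft <- fit_ridge_logistic(design(cbind(cent_done, cent_new)), y, lambda)
          if (is.null(best) || ft$criterion < best$criterion)
            best <- list(j = j, s = s, criterion = ft$criterion, fit = ft)
        }
      }
      if (is.null(best) || best$criterion >= criterion - tol) break
      members <- c(members, best$j); msign <- c(msign, best$s)
      sumcol <- sumcol + best$s * Z[, best$j]
      criterion <- best$criterion
      final_fit <- best$fit
      trace <- c(trace, criterion)
      cand <- setdiff(cand, best$j)
    }
    if (!length(members)) break           # nothing improves: stop opening clusters
    clusters[[k]] <- members; signs[[k]] <- msign; traces[[k]] <- trace
    cent_done <- cbind(cent_done, sumcol / length(members))
    used <- c(used, members)
  }
  if (!length(clusters))
    stop("no taxon decreased the penalized criterion; nothing to cluster")
  colnames(cent_done) <- paste0("cluster", seq_along(clusters))
  rownames(cent_done) <- rownames(Z)

  structure(list(clusters = clusters, signs = signs, lambda = lambda,
                 coefficients = final_fit$coefficients,
                 criterion = criterion, criterion_trace = traces,
                 centroids = cent_done, y = y, z = z,
                 n_fixed = if (is.null(fixed)) 0L else ncol(fixed),
                 fixed_covariates = fixed,
                 sign_flip = sign_flip, tol = tol,
                 call = match.call()),
            class = "pelora")
}

#' @export
print.pelora <- function(x, ...) {
  cat(sprintf("PELORA fit: %d cluster(s), lambda = %g, criterion = %.4f\n",
              length(x$clusters), x$lambda, x$criterion))
  for (k in seq_along(x$clusters))
    cat(sprintf("  cluster %d (%d taxa): %s\n", k, length(x$clusters[[k]]),
                paste(x$clusters[[k]], collapse = ", ")))
  invisible(x)
}

#' @export
coef.pelora <- function(object, ...) {
  cf <- object$coefficients
  names(cf) <- c("(Intercept)",
                 if (object$n_fixed) paste0("fixed", seq_len(object$n_fixed)),
                 paste0("cluster", seq_along(object$clusters)))
  cf
}

#' Per-cluster membership report for a PELORA fit
#'
#' For each cluster, the per-member group means and SDs on the Z scale with
#' a per-member two-group comparison, plus the cluster-centroid group
#' means/SDs and comparison test — the layout of published PELORA cluster
#' tables for case-control microbiome cohorts.
#'
#' @param object a [pelora()] fit.
#' @param ... unused.
#' @return Object of class `summary.pelora`: list of per-cluster data
#'   frames (`member_table`) and `centroid_result` objects (`centroid`).
#' @export
summary.pelora <- function(object, ...) {
  z <- object$z
  out <- lapply(seq_along(object$clusters), function(k) {
    members <- object$clusters[[k]]
    rows <- lapply(members, function(m) {
      v <- if (m %in% colnames(z$values)) z$values[, m] else
        rep(0, nrow(z$values))
      cmp <- compare_groups(v, object$y)
      data.frame(taxon = m,
                 mean0 = mean(v[object$y == 0]), sd0 = stats::sd(v[object$y == 0]),
                 mean1 = mean(v[object$y == 1]), sd1 = stats::sd(v[object$y == 1]),
                 p_value = cmp$p_value, test = cmp$test_used)
    })
    list(member_table = do.call(rbind, rows),
         centroid = centroid(z, members))
  })
  structure(list(clusters = out, lambda = object$lambda), class = "summary.pelora")
}

#' @export
print.summary.pelora <- function(x, ...) {
  for (k in seq_along(x$clusters)) {
    cat(sprintf("== cluster %d ==\n", k))
    print(x$clusters[[k]]$member_table, row.names = FALSE, digits = 3)
    print(x$clusters[[k]]$centroid)
  }
  invisible(x)
}

#' Predicted group probabilities from a PELORA fit
#'
#' @param object a [pelora()] fit.
#' @param newdata optional `zscore_matrix` or plain numeric matrix with the
#'   member taxa as columns (already on the Z scale); default: training data.
#' @param fixed_covariates matrix of fixed covariates for `newdata` when the
#'   fit used any.
#' @param ... unused.
#' @return numeric vector of probabilities of class 1.
#' @export
predict.pelora <- function(object, newdata = NULL, fixed_covariates = NULL, ...) {
  if (is.null(newdata)) {
    cent <- object$centroids
    fixed <- object$fixed_covariates
  } else {
    M <- if (inherits(newdata, "zscore_matrix")) newdata$values else as.matrix(newdata)
    cent <- sapply(seq_along(object$clusters), function(k) {
      members <- object$clusters[[k]]
      if (!all(members %in% colnames(M))) stop("newdata lacks cluster members")
      drop(M[, members, drop = FALSE] %*% object$signs[[k]]) / length(members)
    })
    cent <- matrix(cent, ncol = length(object$clusters))
    fixed <- fixed_covariates
    if (object$n_fixed && is.null(fixed)) stop("fit used fixed covariates; supply them")
  }
  eta <- drop(cbind(1, fixed, cent, deparse.level = 0) %*% object$coefficients)
  stats::plogis(eta)
}

#' @export
fitted.pelora <- function(object, ...) predict.pelora(object)

#' @export
residuals.pelora <- function(object, ...) object$y - fitted.pelora(object)

#' Boxplot of cluster-centroid Z-scores by group
#' @param x a [pelora()] fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.pelora <- function(x, ...) {
  k <- ncol(x$centroids)
  op <- graphics::par(mfrow = c(1, k)); on.exit(graphics::par(op))
  for (j in seq_len(k))
    graphics::boxplot(x$centroids[, j] ~ factor(x$y, 0:1, c("group 0", "group 1")),
                      ylab = "centroid Z-score", xlab = "",
                      main = colnames(x$centroids)[j], ...)
  invisible(x)
}

#' Choose the ridge penalty by bootstrap misclassification
#'
#' For every penalty in `lambda_grid`, PELORA is refit on bootstrap
#' resamples of the cohort and scored by the 0/1 misclassification rate
#' (probability threshold 0.5) on each resample's out-of-bag samples. The
#' penalty attaining the lowest median rate wins; ties break toward the
#' largest penalty (more regularization, stabler clusters).
#'
#' @param z a `zscore_matrix`.
#' @param y 0/1 labels (defaults to `z$group`).
#' @param lambda_grid candidate penalties; default 13 log-spaced values
#'   from 1e-3 to 1e3.
#' @param n_boot number of bootstrap resamples.
#' @param max_clusters passed to [pelora()].
#' @param seed RNG seed for the resampling.
#' @return Object of class `penalty_search`: list with `lambda_grid`,
#'   `rates` (n_boot x grid matrix of OOB misclassification rates),
#'   `median_rates`, `lambda` (the chosen value).
#' @export
tune_penalty <- function(z, y = z$group, lambda_grid = 10^seq(-3, 3, by = 0.5),
                         n_boot = 50L, max_clusters = 2L, seed = 1L) {
  stopifnot(length(lambda_grid) >= 1L, n_boot >= 1L)
  y <- as.numeric(encode_group(y))
  n <- nrow(z$values)
  set.seed(seed)
  rates <- matrix(NA_real_, n_boot, length(lambda_grid))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L && length(setdiff(seq_len(n), idx)) > 0L) break
      message("bootstrap resample degenerate; redrawn")
    }
    oob <- setdiff(seq_len(n), idx)
    zb <- z; zb$values <- z$values[idx, , drop = FALSE]; zb$group <- NULL
    for (g in seq_along(lambda_grid)) {
      fit <- tryCatch(pelora(zb, y[idx], lambda = lambda_grid[g],
                             max_clusters = max_clusters),
                      error = function(e) NULL)
      rates[b, g] <- if (is.null(fit)) 0.5 else {
        p <- predict(fit, newdata = z$values[oob, , drop = FALSE])
        mean((p > 0.5) != y[oob])
      }
    }
  }
  med <- apply(rates, 2L, stats::median)
  best <- max(lambda_grid[med == min(med)])   # tie -> largest lambda
  structure(list(lambda_grid = lambda_grid, rates = rates,
                 median_rates = med, lambda = best),
            class = "penalty_search")
}

#' @export
print.penalty_search <- function(x, ...) {
  cat("penalty search (bootstrap OOB misclassification):\n")
  print(data.frame(lambda = x$lambda_grid, median_rate = x$median_rates),
        row.names = FALSE)
  cat(sprintf("chosen lambda = %g\n", x$lambda))
  invisible(x)
}
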