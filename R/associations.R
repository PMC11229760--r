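#' Taxon-metabolite Spearman association matrix
#'
#' Pairwise Spearman rank correlations between every taxon column and every
#' metabolite column over the shared samples. `rho` is the Pearson
#' correlation of (average-tie) ranks; two-sided p-values come from the
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` approximation on `n - 2` degrees
#' of freedom. Rank correlation is invariant under strictly monotone
#' transforms, so raw percents, logit percents and Z-scores all give the
#' same result. The significance mask applies raw `p < alpha` by default
#' (the published convention); `adjust = "BH"` switches to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param taxa_values samples x taxa numeric matrix.
#' @param metabolite_values samples x compounds numeric matrix, same
#'   samples in the same order.
#' @param alpha significance level for the mask.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Object of class `correlation_result`: list with `rho`, `p`
#'   (taxa x metabolites matrices; `NA` where a column is constant),
#'   `significant` (logical mask), `alpha`, `n`.
#' @export
spearman_matrix <- function(taxa_values, metabolite_values, alpha = 0.05,
                            adjust = "none") {
  A <- as.matrix(taxa_values)
  B <- as.matrix(metabolite_values)
  if (nrow(A) != nrow(B)) stop("sample mismatch between the two blocks")
  n <- nrow(A)
  if (n < 3L) stop("at least 3 samples required")
  const_a <- apply(A, 2L, function(v) length(unique(v)) == 1L)
  const_b <- apply(B, 2L, function(v) length(unique(v)) == 1L)
  if (any(const_a) || any(const_b))
    message("constant column(s): ",
            paste(c(colnames(A)[const_a], colnames(B)[const_b]), collapse = ", "),
            " -> rho undefined (NA)")
  rho <- suppressWarnings(stats::cor(A, B, method = "spearman"))
  rho[const_a, ] <- NA_real_
  rho[, const_b] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  if (adjust != "none")
    p[] <- stats::p.adjust(p, method = adjust)
  structure(list(rho = rho, p = p,
                 significant = !is.na(p) & p < alpha,
                 alpha = alpha, n = n, adjust = adjust),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman associations: %d taxa x %d metabolites (n = %d), %d significant at %s p < %g\n",
              nrow(x$rho), ncol(x$rho), x$n, sum(x$significant),
              if (x$adjust == "none") "raw" else x$adjust, x$alpha))
  invisible(x)
}

#' Long-format table of significant taxon-metabolite pairs
#'
#' @param result a `correlation_result`.
#' @return data frame `taxon`, `metabolite`, `rho`, `p`, sorted by p.
#' @export
significant_pairs <- function(result) {
  idx <- which(result$significant, arr.ind = TRUE)
  out <- data.frame(taxon = rownames(result$rho)[idx[, 1]],
                    metabolite = colnames(result$rho)[idx[, 2]],
                    rho = result$rho[idx], p = result$p[idx])
  out[order(out$p), , drop = FALSE]
}
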