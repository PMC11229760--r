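#' Alpha diversity: Shannon entropy and Chao1 richness
#'
#' Shannon is computed on the composition (natural log; zero entries
#' contribute nothing). Chao1 requires integer counts: with `S_obs` observed
#' taxa, `F1` singletons and `F2` doubletons it is
#' `S_obs + F1^2 / (2 F2)` when `F2 > 0` and `S_obs + F1 (F1 - 1) / 2`
#' when `F2 = 0`. On non-integer input (relative abundances) Chao1 is
#' undefined and returned as `NA`.
#'
#' @param x nonnegative numeric vector (one sample's counts or
#'   proportions/percents) or a matrix with samples in rows.
#' @return For a vector, a named numeric `c(shannon=, chao1=)`; for a
#'   matrix, a data frame with one row per sample.
#' @export
alpha_diversity <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    res <- t(apply(as.matrix(x), 1L, alpha_diversity))
    return(as.data.frame(res))
  }
  x <- as.numeric(x)
  if (any(x < 0)) stop("negative entries")
  if (sum(x) == 0) stop("all-zero sample")
  shannon <- unname(vegan::diversity(x, index = "shannon"))
  is_counts <- all(abs(x - round(x)) < 1e-8)
  chao1 <- if (is_counts) chao1_estimate(round(x)) else NA_real_
  c(shannon = shannon, chao1 = chao1)
}

# classic bias-free Chao1 estimator
chao1_estimate <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}
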