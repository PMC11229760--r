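#' Replace exact-zero abundances by half the dataset minimum
#'
#' A relative abundance of exactly 0% has no logit; following the
#' half-minimum convention for compositional detection limits, every zero
#' entry is replaced by half of the smallest nonzero percent found in the
#' entire matrix (e.g. 0.0001% when the smallest observed value is
#' 0.0002%). Nonzero entries are untouched.
#'
#' @param table an [abundance_table()].
#' @return The table with zeros replaced; the replacement value is attached
#'   as attribute `replacement_value` (`NA` if there were no zeros).
#' @export
replace_zeros <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  nz <- v[v > 0]
  if (!length(nz)) stop("all-zero abundance matrix")
  repl <- min(nz) / 2
  had_zeros <- any(v == 0)
  v[v == 0] <- repl
  table$values <- v
  attr(table, "replacement_value") <- if (had_zeros) repl else NA_real_
  table
}

#' Logit transform and per-feature standardization (Z-scores)
#'
#' Each percent `q` becomes `log(p / (1 - p))` with `p = q / 100`, then each
#' taxon column is standardized to mean 0, sample SD 1 (denominator `n - 1`)
#' over the whole cohort, both groups pooled. Columns that are constant
#' after the logit (e.g. a taxon at 0% everywhere, all entries equal to the
#' replacement value) carry no information and are moved aside with their
#' constant logit value recorded.
#'
#' @param table an [abundance_table()] with zeros already replaced
#'   (see [replace_zeros()]); all entries must lie strictly in (0, 100).
#' @return An object of class `zscore_matrix`: list with `values`
#'   (samples x retained features), `feature_means`, `feature_sds`
#'   (logit-scale statistics of retained features), `dropped_features`
#'   (named numeric of constant logit values), `replacement_value`,
#'   `group`, `rank`.
#' @export
logit_zscore <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (any(v <= 0) || any(v >= 100))
    stop("all percents must lie strictly in (0, 100); replace zeros first")
  l <- stats::qlogis(v / 100)
  mu <- colMeans(l)
  sdv <- apply(l, 2L, stats::sd)
  keep <- sdv > 1e-12
  z <- sweep(sweep(l[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  structure(list(values = z,
                 feature_means = mu[keep],
                 feature_sds = sdv[keep],
                 dropped_features = mu[!keep],
                 replacement_value = attr(table, "replacement_value"),
                 group = table$group,
                 rank = table$rank),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("zscore_matrix: %d samples x %d features (%s rank), %d constant feature(s) dropped\n",
              nrow(x$values), ncol(x$values), x$rank, length(x$dropped_features)))
  invisible(x)
}

#' Full transform pipeline: zero replacement then logit/Z-score
#'
#' @param table an [abundance_table()].
#' @return A `zscore_matrix` (see [logit_zscore()]).
#' @export
transform_abundance <- function(table) {
  logit_zscore(replace_zeros(table))
}

#' Cluster centroid on the Z-score scale
#'
#' The centroid of a taxon cluster is the per-sample unweighted mean of the
#' member Z-scores. Members listed among the transform's dropped (constant)
#' features contribute their constant value, which is 0 after
#' standardization unless overridden through `absent_constants`. Group
#' means/SDs of the centroid and a two-group comparison (see
#' [compare_groups()]) are reported.
#'
#' @param z a `zscore_matrix`.
#' @param members character vector of member taxa.
#' @param absent_constants optional named numeric: a constant Z value to use
#'   for specific members not present as columns of `z`.
#' @return Object of class `centroid_result`: list with `members`,
#'   `values` (per-sample centroid), `group_means`, `group_sds`,
#'   `statistic`, `p_value`, `test_used`.
#' @export
centroid <- function(z, members, absent_constants = NULL) {
  stopifnot(inherits(z, "zscore_matrix"))
  if (!length(members)) stop("empty member set")
  n <- nrow(z$values)
  cols <- matrix(NA_real_, n, length(members),
                 dimnames = list(rownames(z$values), members))
  for (m in members) {
    if (m %in% colnames(z$values)) {
      cols[, m] <- z$values[, m]
    } else if (!is.null(absent_constants) && m %in% names(absent_constants)) {
      cols[, m] <- absent_constants[[m]]
    } else if (m %in% names(z$dropped_features)) {
      cols[, m] <- 0  # a standardized constant feature sits at its mean
    } else {
      stop("unknown cluster member: ", m)
    }
  }
  val <- rowMeans(cols)
  cmp <- compare_groups(val, z$group)
  g <- z$group
  structure(list(members = members,
                 values = val,
                 group_means = c(`0` = mean(val[g == 0L]), `1` = mean(val[g == 1L])),
                 group_sds = c(`0` = stats::sd(val[g == 0L]), `1` = stats::sd(val[g == 1L])),
                 statistic = cmp$statistic, p_value = cmp$p_value,
                 test_used = cmp$test_used),
            class = "centroid_result")
}

#' @export
print.centroid_result <- function(x, ...) {
  cat(sprintf("centroid of %d taxa: group means %.3f vs %.3f (%s, p = %.3g)\n",
              length(x$members), x$group_means[["0"]], x$group_means[["1"]],
              x$test_used, x$p_value))
  invisible(x)
}

#' Two-group location comparison with automatic test choice
#'
#' Welch's unequal-variance two-sample t-test by default; when either group
#' has zero variance (typically a taxon that is 0% throughout one group,
#' hence constant on the Z scale there) the t-test denominator degenerates
#' and the Mann-Whitney U test is used instead. Two-sided p-values.
#'
#' @param x numeric values (e.g. per-sample Z-scores or centroid values).
#' @param group 0/1 labels aligned with `x`.
#' @param test `"auto"` (default switch described above), `"t"`, or
#'   `"mann-whitney"` to force a test.
#' @return list with `statistic`, `p_value`, `test_used`.
#' @export
compare_groups <- function(x, group, test = c("auto", "t", "mann-whitney")) {
  test <- match.arg(test)
  group <- encode_group(group)
  x0 <- x[group == 0L]; x1 <- x[group == 1L]
  if (length(x0) < 2L || length(x1) < 2L) stop("each group needs at least 2 samples")
  if (test == "auto")
    test <- if (stats::var(x0) == 0 || stats::var(x1) == 0) "mann-whitney" else "t"
  if (test == "t") {
    ht <- stats::t.test(x0, x1, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test_used = "t")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x0, x1, exact = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_used = "mann-whitney")
  }
}

#' Constant Z-score of a feature absent from one group
#'
#' A taxon observed at 0% in every sample of one group is constant on the
#' logit scale within that group; pooled standardization then pins its
#' within-group Z at the constant `c` solving
#' `n_absent * c + n_other * mean_other = 0` (the pooled mean of a Z-score
#' column is zero). Used to reconstruct cluster centroids from published
#' per-member group means in which such a member is marked "Absent".
#'
#' @param n_absent size of the group where the taxon is absent.
#' @param n_other size of the other group.
#' @param mean_other the other group's mean Z-score for the taxon.
#' @return the constant `c`.
#' @export
impute_absent_z <- function(n_absent, n_other, mean_other) {
  -n_other * mean_other / n_absent
}

#' Cluster-centroid group means from published member group means
#'
#' By linearity, the group mean of a cluster centroid equals the unweighted
#' mean of the member group means. Members absent from one group (reported
#' without a mean there) get the pooled-standardization constant from
#' [impute_absent_z()] computed off the opposite group's mean.
#'
#' @param mean0,mean1 per-member mean Z-scores in groups 0 and 1 (`NA`
#'   marks a member absent from that group).
#' @param n sizes of groups 0 and 1, default the 25 / 28 split of the
#'   pancreatic-cancer cohort this package emulates.
#' @return named numeric `c("0" = , "1" = )` of centroid group means.
#' @export
centroid_group_means <- function(mean0, mean1, n = c(25L, 28L)) {
  stopifnot(length(mean0) == length(mean1))
  both <- is.na(mean0) & is.na(mean1)
  if (any(both)) stop("a member must have a mean in at least one group")
  mean0[is.na(mean0)] <- impute_absent_z(n[1], n[2], mean1[is.na(mean0)])
  mean1[is.na(mean1)] <- impute_absent_z(n[2], n[1], mean0[is.na(mean1)])
  c(`0` = mean(mean0), `1` = mean(mean1))
}
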