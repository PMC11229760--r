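#' Construct a relative-abundance table
#'
#' Container for a samples x taxa matrix of relative abundances on the
#' percent scale (0-100) at one taxonomic rank, together with a binary
#' group label per sample (0 = non-metastatic, 1 = metastatic in the
#' case-control design this package targets).
#'
#' @param values numeric matrix, samples in rows, taxa in columns, percent
#'   scale. Row and column names are required and must be unique.
#' @param group per-sample labels: 0/1, logical, or a two-level factor /
#'   character vector (the second sorted level is coded 1).
#' @param rank taxonomic rank tag, one of `"phylum"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @param sum_tolerance per-sample row sums outside
#'   `100 +/- sum_tolerance` are recorded as validation warnings (the table
#'   is still returned; compositions lacking a remainder column legitimately
#'   sum below 100).
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `group` (named integer 0/1), `rank`, and `validation`
#'   (character vector of recorded warnings).
#' @export
abundance_table <- function(values, group,
                            rank = c("phylum", "family", "genus", "species"),
                            sum_tolerance = 1.0) {
  rank <- match.arg(rank)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicated taxon identifiers within rank")
  if (any(!is.finite(values)))
    stop("non-finite abundance values")
  if (any(values < 0))
    stop("negative relative abundances")
  group <- encode_group(group)
  if (length(group) != nrow(values))
    stop("'group' length must equal the number of samples")
  if (is.null(names(group))) names(group) <- rownames(values)
  if (!identical(names(group), rownames(values)))
    stop("group labels must be named by, and aligned to, the sample ids")
  if (anyNA(group))
    stop("missing group label")

  log <- character(0)
  rs <- rowSums(values)
  off <- which(abs(rs - 100) > sum_tolerance)
  if (length(off))
    log <- c(log, sprintf("row sum outside tolerance for sample '%s' (%.4f)",
                          rownames(values)[off], rs[off]))
  structure(list(values = values, group = group, rank = rank,
                 validation = log),
            class = "abundance_table")
}

encode_group <- function(group) {
  if (is.factor(group)) group <- as.character(group)
  if (is.character(group)) {
    lev <- sort(unique(group))
    if (length(lev) > 2) stop("more than two group levels")
    g <- as.integer(group == lev[length(lev)])
    names(g) <- names(group)
    return(g)
  }
  g <- as.integer(group)
  if (!all(g %in% c(0L, 1L) | is.na(g))) stop("numeric group labels must be 0/1")
  names(g) <- names(group)
  g
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s rank)\n",
              nrow(x$values), ncol(x$values), x$rank))
  tab <- table(factor(x$group, levels = 0:1))
  cat(sprintf("  groups: 0 (n=%d), 1 (n=%d)\n", tab[["0"]], tab[["1"]]))
  if (length(x$validation))
    cat(sprintf("  %d validation warning(s) recorded\n", length(x$validation)))
  invisible(x)
}

#' Read a relative-abundance table with sample metadata
#'
#' Reads a tab-separated table (samples in rows, header of taxon names,
#' first column of sample identifiers) plus a metadata table with columns
#' `sample_id` and `group`, and returns a validated [abundance_table()].
#' Samples are aligned to the metadata order by identifier, never by
#' position.
#'
#' @param path abundance TSV path.
#' @param rank taxonomic rank tag.
#' @param metadata_path metadata TSV path (`sample_id`, `group` columns;
#'   group coded 0/1 or as two labels such as `PC` / `PC_met`).
#' @param ... passed to [abundance_table()].
#' @return An [abundance_table()]. Samples present in the abundance file but
#'   absent from the metadata are dropped and reported in the validation log;
#'   metadata samples missing from the abundance file are a hard error.
#' @export
read_abundance_table <- function(path, rank, metadata_path, ...) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must have 'sample_id' and 'group' columns")
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  missing <- setdiff(meta$sample_id, rownames(raw))
  if (length(missing))
    stop("samples in metadata without abundance rows: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(rownames(raw), meta$sample_id)
  vals <- as.matrix(raw[meta$sample_id, , drop = FALSE])
  grp <- meta$group
  suppressWarnings(gnum <- as.numeric(grp))
  if (!anyNA(gnum)) grp <- as.integer(gnum)
  names(grp) <- meta$sample_id
  tab <- abundance_table(vals, grp, rank = rank, ...)
  if (length(extra))
    tab$validation <- c(tab$validation,
                        sprintf("sample '%s' had no metadata and was dropped", extra))
  tab
}

#' Write an abundance table and its metadata to TSV
#'
#' Inverse of [read_abundance_table()]: values round-trip exactly
#' (full double precision).
#'
#' @param table an [abundance_table()].
#' @param path abundance TSV destination.
#' @param metadata_path metadata TSV destination.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   format(table$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = rownames(table$values), group = table$group)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BIOM 2.1 abundance table
#'
#' Optional reader producing the same container as
#' [read_abundance_table()]; requires the `biomformat` package.
#'
#' @inheritParams read_abundance_table
#' @return An [abundance_table()].
#' @export
read_abundance_biom <- function(path, rank, metadata_path, ...) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))  # biom stores taxa x samples
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                     tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_abundance_table(tmp, rank = rank, metadata_path = metadata_path, ...)
}

#' Per-group composition summary with an "Others" category
#'
#' Folds taxa whose cohort-wide mean relative abundance is below a percent
#' threshold into a single `Others` category and reports per-group mean
#' relative abundances, the quantity stacked-bar composition figures
#' display. Default thresholds by rank: 1% (phylum, family),
#' 0.5% (genus), 0.1% (species).
#'
#' @param table an [abundance_table()].
#' @param threshold percent cutoff on the cohort-wide mean; `NULL` picks the
#'   rank default.
#' @return An object of class `composition_summary`: list with `means`
#'   (taxa+Others x 2 group matrix of mean percent), `others_members`,
#'   `threshold`.
#' @export
aggregate_others <- function(table, threshold = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table$values) == 0L || nrow(table$values) == 0L)
    stop("empty abundance table")
  if (is.null(threshold))
    threshold <- switch(table$rank,
                        phylum = 1, family = 1, genus = 0.5, species = 0.1)
  if (threshold <= 0) stop("'threshold' must be positive")
  cohort_mean <- colMeans(table$values)
  fold <- cohort_mean < threshold
  g <- table$group
  gm <- function(keep) {
    m0 <- colMeans(table$values[g == 0L, keep, drop = FALSE])
    m1 <- colMeans(table$values[g == 1L, keep, drop = FALSE])
    cbind(`0` = m0, `1` = m1)
  }
  means <- gm(!fold)
  others <- c(`0` = sum(gm(fold)[, "0"]), `1` = sum(gm(fold)[, "1"]))
  if (any(fold)) means <- rbind(means, Others = others)
  structure(list(means = means,
                 others_members = colnames(table$values)[fold],
                 threshold = threshold),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("composition_summary: %d categories (threshold %g%%, %d taxa folded into Others)\n",
              nrow(x$means), x$threshold, length(x$others_members)))
  print(utils::head(round(x$means, 3), 15))
  invisible(x)
}

#' Write a composition summary to TSV
#' @param summary a `composition_summary`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_composition_summary <- function(summary, path) {
  df <- data.frame(taxon = rownames(summary$means), summary$means,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
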