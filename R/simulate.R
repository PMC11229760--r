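#' Specification of a synthetic case-control cohort
#'
#' Defines the generative model [simulate_cohort()] draws from: per-taxon
#' Gaussian latents on the logit scale with heterogeneous means and
#' variances, closed into percent compositions, an optional taxon cluster
#' shifted between groups, an optional pairwise feature interaction driving
#' the labels through a logistic rule, detection-limit zeroing, and
#' metabolite columns rank-correlated with chosen taxa. Defaults mirror a
#' 53-sample two-group pancreatic-cancer cohort (25 vs 28) with
#' right-skewed multi-rank abundance tables.
#'
#' @param n_per_group sample counts for groups 0 and 1.
#' @param n_taxa named integer vector of taxa per rank (names among
#'   phylum/family/genus/species).
#' @param planted_cluster `NULL` or
#'   `list(rank =, taxa = <indices or count>, delta =)`: the named taxa get
#'   `delta` added to their logit-scale latent in group 1.
#' @param planted_interaction `NULL` or `list(rank =, features = <2
#'   indices>, beta0 =, beta_main = <2>, beta_int =)`: labels are then
#'   drawn from `plogis(beta0 + beta_main %*% s + beta_int * s1 * s2)`
#'   with `s1`, `s2` the standardized observed logit-scale abundances of
#'   the two features (after closure and detection-limit zeroing, with the
#'   half-minimum replacement applied), i.e. the rule acts on exactly the
#'   variables a downstream classifier sees; otherwise labels follow the
#'   group assignment.
#' @param zero_rate fraction of entries pushed to 0% by the detection
#'   limit (the limit is set at the `zero_rate` quantile of all generated
#'   percents), in `[0, 1)`.
#' @param n_metabolites metabolite columns to generate.
#' @param planted_assoc `NULL` or `list(rank =, taxon =, metabolite =,
#'   rho =)`: target Spearman correlation (|rho| <= 0.99) between the
#'   taxon's latent and the metabolite, induced through a shared Gaussian
#'   factor.
#' @param seed mandatory integer seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_per_group = c(25L, 28L),
                            n_taxa = c(phylum = 20L, family = 60L,
                                       genus = 150L, species = 300L),
                            planted_cluster = NULL,
                            planted_interaction = NULL,
                            zero_rate = 0.3,
                            n_metabolites = 0L,
                            planted_assoc = NULL,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 2L),
            zero_rate >= 0, zero_rate < 1,
            all(names(n_taxa) %in% c("phylum", "family", "genus", "species")))
  if (!is.null(planted_cluster)) {
    stopifnot(is.finite(planted_cluster$delta),
              planted_cluster$rank %in% names(n_taxa))
    if (length(planted_cluster$taxa) == 1L && planted_cluster$taxa <= 1e6)
      planted_cluster$taxa <- seq_len(planted_cluster$taxa)
  }
  if (!is.null(planted_interaction)) {
    pi0 <- planted_interaction
    planted_interaction <- list(
      rank = pi0$rank, features = pi0$features,
      beta0 = if (is.null(pi0$beta0)) 0 else pi0$beta0,
      beta_main = if (is.null(pi0$beta_main)) c(1.5, 1.5) else pi0$beta_main,
      beta_int = if (is.null(pi0$beta_int)) 4.5 else pi0$beta_int)
    stopifnot(length(planted_interaction$features) == 2L)
  }
  if (!is.null(planted_assoc) && abs(planted_assoc$rho) > 0.99)
    stop("infeasible target rho (|rho| > 0.99)")
  structure(list(n_per_group = as.integer(n_per_group), n_taxa = n_taxa,
                 planted_cluster = planted_cluster,
                 planted_interaction = planted_interaction,
                 zero_rate = zero_rate,
                 n_metabolites = as.integer(n_metabolites),
                 planted_assoc = planted_assoc,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw a synthetic cohort with ground truth
#'
#' See [simulation_spec()] for the generative model. Per rank: latent
#' `L[i, t] = mu_t + delta * 1[group_i = 1, t planted] + sd_t * eps`, with
#' `mu_t ~ N(-4, 2.5^2)` and a base scale `~ U(0.5, 1.5)` damped for
#' abundant taxa (`sd_t` is multiplied by `clamp(-mu_t / 4, 0.3, 1)`:
#' dominant core taxa are more stable than rare ones, which also keeps the
#' closure denominator from being dominated by a few volatile taxa).
#' Planted taxa (cluster members, interaction features, association
#' anchors) form an exchangeable module at fixed `mu = -3` with unit base
#' scale. Percents are the softmax closure
#' `100 * exp(L) / rowsum(exp(L))` (rows sum to 100 exactly); entries below
#' the detection limit are then set to 0%.
#'
#' @param spec a [simulation_spec()].
#' @return Object of class `synthetic_cohort`: list with `tables` (one
#'   [abundance_table()] per rank), `metabolites` (matrix or `NULL`),
#'   `labels`, and `truth` (planted cluster taxa, delta, interaction rule,
#'   association target) sufficient to score recovery.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n0 <- spec$n_per_group[1]; n1 <- spec$n_per_group[2]
  n <- n0 + n1
  group <- c(rep(0L, n0), rep(1L, n1))
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(group) <- sample_ids

  percents <- list(); tables <- list()
  truth <- list(delta = NULL, cluster = NULL, interaction = NULL, assoc = NULL)

  for (rk in names(spec$n_taxa)) {
    p <- spec$n_taxa[[rk]]
    taxa <- sprintf("%s_%03d", rk, seq_len(p))
    mu <- stats::rnorm(p, -4, 2.5)
    sdv <- stats::runif(p, 0.5, 1.5)
    # planted structure forms an exchangeable module of moderately rare,
    # reliably detectable taxa: fixed baseline and unit latent scale, so
    # the shift delta is homogeneous across members in standardized units;
    # structure planted below the detection limit is unidentifiable
    planted <- integer(0)
    if (!is.null(spec$planted_cluster) && spec$planted_cluster$rank == rk)
      planted <- c(planted, spec$planted_cluster$taxa)
    if (!is.null(spec$planted_interaction) && spec$planted_interaction$rank == rk)
      planted <- c(planted, spec$planted_interaction$features)
    if (!is.null(spec$planted_assoc) && spec$planted_assoc$rank == rk)
      planted <- c(planted, spec$planted_assoc$taxon)
    planted <- unique(planted)
    if (length(planted)) {
      mu[planted] <- -3
      sdv[planted] <- 1
    }
    # abundant core taxa fluctuate less than rare ones
    sdv <- sdv * pmin(1, pmax(0.3, -mu / 4))
    L <- matrix(stats::rnorm(n * p), n, p)
    L <- sweep(L, 2L, sdv, "*")
    L <- sweep(L, 2L, mu, "+")
    dimnames(L) <- list(sample_ids, taxa)
    if (!is.null(spec$planted_cluster) && spec$planted_cluster$rank == rk) {
      pl <- spec$planted_cluster$taxa
      L[group == 1L, pl] <- L[group == 1L, pl] + spec$planted_cluster$delta
      truth$cluster <- taxa[pl]
      truth$delta <- spec$planted_cluster$delta
    }
    E <- exp(L)
    pct <- 100 * E / rowSums(E)
    if (spec$zero_rate > 0) {
      thr <- stats::quantile(pct, spec$zero_rate, names = FALSE)
      pct[pct < thr] <- 0
    }
    percents[[rk]] <- pct
  }

  # observed feature on the analysis scale: logit of the closed percent
  # with the dataset half-minimum replacing zeros
  observed_logit <- function(rk, col) {
    pct <- percents[[rk]]
    repl <- min(pct[pct > 0]) / 2
    v <- pct[, col]
    stats::qlogis(pmax(v, repl) / 100)
  }

  labels <- group
  if (!is.null(spec$planted_interaction)) {
    pi0 <- spec$planted_interaction
    s1 <- scale(observed_logit(pi0$rank, pi0$features[1]))[, 1]
    s2 <- scale(observed_logit(pi0$rank, pi0$features[2]))[, 1]
    eta <- pi0$beta0 + pi0$beta_main[1] * s1 + pi0$beta_main[2] * s2 +
      pi0$beta_int * s1 * s2
    labels <- stats::rbinom(n, 1L, stats::plogis(eta))
    names(labels) <- sample_ids
    if (length(unique(labels)) < 2L)
      labels[sample.int(n, 1L)] <- 1L - labels[[1L]]
    truth$interaction <- list(
      features = colnames(percents[[pi0$rank]])[pi0$features],
      beta0 = pi0$beta0, beta_main = pi0$beta_main, beta_int = pi0$beta_int)
  }

  for (rk in names(spec$n_taxa))
    tables[[rk]] <- abundance_table(percents[[rk]], labels, rank = rk,
                                    sum_tolerance = 100)

  metabolites <- NULL
  if (spec$n_metabolites > 0L) {
    M <- matrix(stats::rnorm(n * spec$n_metabolites), n, spec$n_metabolites,
                dimnames = list(sample_ids,
                                sprintf("met_%03d", seq_len(spec$n_metabolites))))
    if (!is.null(spec$planted_assoc)) {
      pa <- spec$planted_assoc
      a <- 2 * sin(pi * pa$rho / 6)       # Pearson loading hitting Spearman rho
      anchor <- scale(observed_logit(pa$rank, pa$taxon))[, 1]
      M[, pa$metabolite] <- a * anchor + sqrt(1 - a^2) * stats::rnorm(n)
      truth$assoc <- list(taxon = colnames(percents[[pa$rank]])[pa$taxon],
                          metabolite = colnames(M)[pa$metabolite],
                          rho = pa$rho)
    }
    metabolites <- exp(3 + M)             # positive intensity scale
  }

  structure(list(tables = tables, metabolites = metabolites,
                 labels = labels, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples (%d/%d), ranks: %s\n",
              length(x$labels), sum(x$labels == 0L), sum(x$labels == 1L),
              paste(names(x$tables), collapse = ", ")))
  if (!is.null(x$truth$cluster))
    cat(sprintf("  planted cluster: %d taxa, delta = %g\n",
                length(x$truth$cluster), x$truth$delta))
  if (!is.null(x$truth$interaction))
    cat(sprintf("  planted interaction: %s\n",
                paste(x$truth$interaction$features, collapse = " : ")))
  invisible(x)
}

#' Score recovery of planted structure
#'
#' For taxon sets, the overlap fraction `|found ∩ truth| / |truth|` and
#' the Jaccard index. For an `interaction_stability` result, whether the
#' planted pair is among the interactions at or above the stability
#' threshold.
#'
#' @param found a character vector of taxa, or a [mine_interactions()]
#'   result.
#' @param truth the planted taxon set, or the planted feature pair.
#' @param stability_threshold threshold for the interaction indicator.
#' @return list with `overlap` and `jaccard` (set case), or `found`
#'   (logical), `stability` (of the planted pair, 0 if absent) in the
#'   interaction case.
#' @export
score_recovery <- function(found, truth, stability_threshold = 0.5) {
  if (inherits(found, "interaction_stability")) {
    sets <- attr(found, "sets")
    key <- paste(sort(truth), collapse = "|")
    hit <- vapply(sets, function(s) paste(sort(s), collapse = "|") == key,
                  logical(1))
    stab <- if (any(hit)) max(found$stability[hit]) else 0
    return(list(found = stab >= stability_threshold, stability = stab))
  }
  inter <- length(intersect(found, truth))
  list(overlap = inter / length(truth),
       jaccard = inter / length(union(found, truth)))
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits the same formats [read_abundance_table()] consumes
#' (`<rank>.tsv` + `metadata.tsv`), `metabolites.tsv` when present, and a
#' `truth.json` ground-truth record.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  for (rk in names(cohort$tables))
    write_abundance_table(cohort$tables[[rk]],
                          file.path(dir, paste0(rk, ".tsv")), meta_path)
  if (!is.null(cohort$metabolites)) {
    df <- data.frame(sample_id = rownames(cohort$metabolites),
                     cohort$metabolites, check.names = FALSE)
    utils::write.table(df, file.path(dir, "metabolites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
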