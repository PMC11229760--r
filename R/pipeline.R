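#' Recover the logit-scale feature matrix behind a Z-score matrix
#'
#' Undoes the per-feature standardization (`z * sd + mean`), returning the
#' logit-transformed abundances. Forests are invariant to this affine
#' per-feature rescaling, but interpretation axes (ALE, PDP) on the logit
#' scale match the transform convention used throughout.
#'
#' @param z a `zscore_matrix`.
#' @return numeric matrix, samples x retained features.
#' @export
logit_values <- function(z) {
  stopifnot(inherits(z, "zscore_matrix"))
  sweep(sweep(z$values, 2L, z$feature_sds, "*"), 2L, z$feature_means, "+")
}

#' Build a pipeline configuration
#'
#' Either reads a YAML file or assembles the nested list directly. The
#' configuration names the inputs (abundance/metadata paths per rank, or a
#' [simulation_spec()] to generate them), toggles the two analysis
#' branches, carries their parameters, and fixes one root seed from which
#' every module's seed is derived (see [module_seed()]).
#'
#' @param path YAML file path, or `NULL`.
#' @param ... fields overriding / replacing the file contents: `seed`,
#'   `out_dir`, `input` (list with either `simulate` = [simulation_spec()]
#'   or `abundance` = named rank->path list plus `metadata`, optionally
#'   `metabolites`), `ranks`, `pelora`, `irf`, `interpret`,
#'   `associations`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  over <- list(...)
  cfg[names(over)] <- over
  defaults <- list(
    ranks = NULL,
    pelora = list(enabled = TRUE, lambda = 1, tune = FALSE,
                  lambda_grid = 10^seq(-3, 3, by = 0.5), n_boot = 20L,
                  max_clusters = 2L),
    irf = list(enabled = TRUE, K = 5L, n_trees = 500L, mine = TRUE,
               n_boot = 30L, rit_depth = 5L, rit_branch = 2L,
               n_rit_trees = 500L),
    interpret = list(enabled = TRUE, n_bins = 20L, grid_size = 20L,
                     vimp_threshold = 10, stability_threshold = 0.70,
                     max_features = 5L),
    associations = list(enabled = TRUE, alpha = 0.05))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (f in setdiff(names(defaults[[nm]]), names(cfg[[nm]])))
        cfg[[nm]][[f]] <- defaults[[nm]][[f]]
  }
  if (is.null(cfg$seed)) stop("config needs a root 'seed'")
  if (is.null(cfg$out_dir)) stop("config needs an 'out_dir'")
  if (is.null(cfg$input)) stop("config needs an 'input' block")
  if (is.null(cfg$input$simulate)) {
    for (p in c(unlist(cfg$input$abundance), cfg$input$metadata,
                cfg$input$metabolites))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(cfg, class = "pipeline_config")
}

#' Per-module seed derived from the root seed
#'
#' Deterministic hash `(root * 7919 + sum of the module name's UTF-8
#' codes * 131) mod (2^31 - 1)`, so modules never share a stream and a
#' single root seed reproduces the whole run.
#'
#' @param root integer root seed.
#' @param module module name.
#' @return a positive integer seed.
#' @export
module_seed <- function(root, module) {
  h <- (as.numeric(root) * 7919 + sum(utf8ToInt(module)) * 131) %% 2147483647
  as.integer(h) + 1L
}

#' Run the full two-branch analysis pipeline
#'
#' Reads (or simulates) the cohort, transforms each requested rank
#' (zero replacement, logit, Z-score), and runs the two branches
#' independently on the same transformed matrix: PELORA supervised
#' clustering, and iRF with interaction mining plus ALE/PDP
#' interpretation; taxon-metabolite Spearman associations are computed for
#' the iRF-selected taxa when a metabolite matrix is available. The two
#' branches never feed each other. All numeric outputs are written under
#' `out_dir` together with a `manifest.json` recording versions, seeds,
#' parameters and file checksums; on a stage error the manifest (with the
#' stages completed so far) is still written before the error propagates.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "microsig",
    version = as.character(utils::packageVersion("microsig")),
    seed = config$seed,
    parameters = config[c("pelora", "irf", "interpret", "associations")],
    stages = character(0))
  done <- function(stage) manifest$stages <<- c(manifest$stages, stage)
  finish <- function() {
    files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    sums <- tools::md5sum(files)
    names(sums) <- sub(paste0("^", out, "/?"), "", names(sums))
    manifest$checksums <<- as.list(sums)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  completed <- FALSE
  on.exit(if (!completed) finish())     # a failed stage still leaves a manifest

  tsv <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  json <- function(x, name) {
    jsonlite::write_json(x, file.path(out, name), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }

  # ---- input stage -------------------------------------------------------
  if (!is.null(config$input$simulate)) {
    spec <- config$input$simulate
    if (!inherits(spec, "simulation_spec"))
      spec <- do.call(simulation_spec,
                      c(spec, list(seed = module_seed(config$seed, "simulate"))))
    cohort <- simulate_cohort(spec)
    tables <- cohort$tables
    metabolites <- cohort$metabolites
    json(cohort$truth, "truth.json")
  } else {
    ranks <- names(config$input$abundance)
    tables <- lapply(stats::setNames(ranks, ranks), function(rk)
      read_abundance_table(config$input$abundance[[rk]], rank = rk,
                           metadata_path = config$input$metadata))
    metabolites <- if (!is.null(config$input$metabolites)) {
      m <- utils::read.delim(config$input$metabolites, check.names = FALSE,
                             row.names = 1)
      as.matrix(m)
    }
  }
  ranks <- if (is.null(config$ranks)) names(tables) else config$ranks
  done("input")

  for (rk in ranks) {
    tab <- tables[[rk]]
    z <- transform_abundance(tab)
    tsv(data.frame(sample_id = rownames(z$values), z$values,
                   check.names = FALSE), sprintf("%s_zscores.tsv", rk))
    json(list(replacement_value = z$replacement_value,
              feature_means = as.list(z$feature_means),
              feature_sds = as.list(z$feature_sds),
              dropped_features = as.list(z$dropped_features)),
         sprintf("%s_transform.json", rk))
    done(paste0("transform:", rk))

    irf_fit <- NULL
    if (isTRUE(config$irf$enabled)) {
      cfg <- config$irf
      L <- logit_values(z)
      irf_fit <- suppressWarnings(
        irf(L, z$group, K = cfg$K, n_trees = cfg$n_trees,
            seed = module_seed(config$seed, paste0("irf:", rk))))
      inter <- if (isTRUE(cfg$mine))
        mine_interactions(L, z$group, K = cfg$K, n_boot = cfg$n_boot,
                          n_trees = cfg$n_trees, rit_depth = cfg$rit_depth,
                          rit_branch = cfg$rit_branch,
                          n_rit_trees = cfg$n_rit_trees,
                          seed = module_seed(config$seed, paste0("rit:", rk)))
      json(list(auc = irf_fit$auc[["auc"]],
                ci = c(irf_fit$auc[["ci_lo"]], irf_fit$auc[["ci_hi"]]),
                vimp_relative = as.list(round(irf_fit$vimp_relative, 6)),
                interactions = if (!is.null(inter))
                  inter[, c("interaction", "order", "stability")]),
           sprintf("%s_irf.json", rk))
      tsv(data.frame(sample_id = names(irf_fit$oob_probabilities),
                     oob_probability = irf_fit$oob_probabilities),
          sprintf("%s_oob.tsv", rk))
      if (!is.null(inter))
        tsv(interaction_edges(inter, 0.5), sprintf("%s_edges.tsv", rk))
      done(paste0("irf:", rk))

      if (isTRUE(config$interpret$enabled)) {
        icfg <- config$interpret
        pfun <- function(m) predict(irf_fit, m)
        feats <- utils::head(select_ale_features(irf_fit, icfg$vimp_threshold),
                             icfg$max_features)
        for (f in feats) {
          cur <- ale_curve(pfun, L, f, n_bins = icfg$n_bins)
          tsv(data.frame(upper_edge = cur$edges[-1], effect = cur$effect,
                         count = cur$counts),
              sprintf("%s_ale_%s.tsv", rk, f))
        }
        cells <- list()
        if (!is.null(inter)) {
          for (pr in select_pdp_pairs(inter, icfg$stability_threshold)) {
            sur <- pdp_surface(pfun, L, pr, grid_size = icfg$grid_size)
            tsv(data.frame(x1 = rep(sur$grid1, length(sur$grid2)),
                           x2 = rep(sur$grid2, each = length(sur$grid1)),
                           probability = as.vector(sur$values)),
                sprintf("%s_pdp_%s_%s.tsv", rk, pr[1], pr[2]))
            hr <- which(sur$high_risk, arr.ind = TRUE)
            if (nrow(hr))
              cells[[paste(pr, collapse = ":")]] <-
                data.frame(x1 = sur$grid1[hr[, 1]], x2 = sur$grid2[hr[, 2]],
                           probability = sur$values[hr])
          }
        }
        json(cells, sprintf("%s_highrisk.json", rk))
        done(paste0("interpret:", rk))
      }
    }

    if (isTRUE(config$pelora$enabled)) {
      cfg <- config$pelora
      lambda <- cfg$lambda
      if (isTRUE(cfg$tune)) {
        search <- tune_penalty(z, lambda_grid = cfg$lambda_grid,
                               n_boot = cfg$n_boot,
                               max_clusters = cfg$max_clusters,
                               seed = module_seed(config$seed,
                                                  paste0("pelora:", rk)))
        lambda <- search$lambda
      }
      fit <- pelora(z, lambda = lambda, max_clusters = cfg$max_clusters)
      json(list(lambda = lambda, clusters = fit$clusters,
                coefficients = as.numeric(coef(fit)),
                criterion_trace = fit$criterion_trace),
           sprintf("%s_pelora.json", rk))
      tsv(data.frame(sample_id = rownames(fit$centroids), fit$centroids,
                     check.names = FALSE), sprintf("%s_centroids.tsv", rk))
      sm <- summary(fit)
      rep_df <- do.call(rbind, lapply(seq_along(sm$clusters), function(k)
        cbind(cluster = k, sm$clusters[[k]]$member_table)))
      tsv(rep_df, sprintf("%s_pelora_report.tsv", rk))
      done(paste0("pelora:", rk))
    }

    if (isTRUE(config$associations$enabled) && !is.null(metabolites)) {
      L <- logit_values(z)
      taxa <- if (!is.null(irf_fit)) {
        sel <- select_ale_features(irf_fit, config$interpret$vimp_threshold)
        if (length(sel)) sel else colnames(L)
      } else colnames(L)
      res <- spearman_matrix(L[, taxa, drop = FALSE],
                             metabolites[rownames(L), , drop = FALSE],
                             alpha = config$associations$alpha)
      tsv(data.frame(taxon = rownames(res$rho), res$rho, check.names = FALSE),
          sprintf("%s_spearman_rho.tsv", rk))
      tsv(data.frame(taxon = rownames(res$p), res$p, check.names = FALSE),
          sprintf("%s_spearman_p.tsv", rk))
      tsv(significant_pairs(res), sprintf("%s_spearman_pairs.tsv", rk))
      done(paste0("associations:", rk))
    }
  }
  finish()
  completed <- TRUE
  invisible(manifest)
}
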