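# End-to-end orchestration: filter -> log10 -> impute, then the univariate,
# PCA and random-forest arms on the imputed matrix, and the network arm
# (PCLRC per group -> connectivity / differential connectivity -> COVSCA ->
# overrepresentation).  All outputs are plain-text files plus a JSON run
# manifest; every randomised stage consumes a seed derived from the master
# seed.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the documented defaults; pass
#' overrides through `run_pipeline`'s `config` argument (or a YAML file
#' with the same structure).
#'
#' @return Nested list of stage parameter blocks.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    input = list(
      synthetic = TRUE,
      synthetic_config = list(),   # overrides for synthetic_config()
      protein_table = NULL, design = NULL, annotation = NULL
    ),
    filter = list(min_valid = 25),
    impute = list(sweeps = 20, ridge_lambda = 1, n_predictors = 20,
                  average_last = 5),
    univariate = list(candidate_alpha = 0.05, dunn_family = "pooled"),
    pca = list(n_components = 10),
    rf = list(enabled = TRUE, n_trees = 500, n_permutations = 1000),
    network = list(enabled = TRUE, n_iterations = 1000,
                   subsample_fraction = 0.75, keep_fraction = 0.30,
                   tau = 0.99, delta_threshold = 50,
                   reference_group = "M-/C-",
                   dc_permutations = 0, dc_iterations = 100),
    covsca = list(enabled = TRUE, L = 2, n_starts = 20, max_iter = 500,
                  tol = 1e-8),
    enrichment = list(enabled = TRUE)
  )
}

# Recursive default merge.
merge_config <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Executes filter -> log10 -> imputation and the enabled analysis arms,
#' writing every result table under `outdir` together with `manifest.json`
#' (stages, parameters, seeds) and `pipeline.log` (per-stage timings).
#' Identical configuration and seed reproduce identical output files; the
#' log file is the only output carrying wall-clock times.
#'
#' @param config A configuration list (merged over
#'   [default_pipeline_config()]) or the path of a YAML file with the same
#'   structure.
#' @param outdir Output directory, created if absent.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- cfg$seed
  log_lines <- character(0)
  t0 <- Sys.time()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%7.2fs] %s: %s",
                            as.numeric(difftime(Sys.time(), t0, units = "secs")),
                            stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stage_stop(stage, conditionMessage(e))
    })
  }
  manifest <- list(stages = list(), seed = seed)

  ## ---- input -------------------------------------------------------------
  if (isTRUE(cfg$input$synthetic)) {
    sc_args <- merge_config(list(seed = derive_seed(seed, "synthetic")),
                            cfg$input$synthetic_config)
    scfg <- do.call(synthetic_config, sc_args)
    ds <- run_stage("input", generate_lfq_dataset(scfg))
    abundance <- ds$abundance
    design <- ds$design
    annotation <- ds$annotation
    note("input", sprintf("synthetic dataset: %d samples x %d proteins",
                          nrow(abundance$values), ncol(abundance$values)))
  } else {
    abundance <- run_stage("input", read_protein_table(cfg$input$protein_table))
    design <- run_stage("input", read_design_table(cfg$input$design))
    annotation <- if (!is.null(cfg$input$annotation)) {
      run_stage("input", read_annotation_table(cfg$input$annotation))
    } else {
      data.frame(protein_id = character(0), keyword = character(0))
    }
    note("input", sprintf("read %d samples x %d proteins",
                          nrow(abundance$values), ncol(abundance$values)))
  }

  ## ---- preprocess: filter -> log10 -> impute ------------------------------
  filtered <- run_stage("preprocess",
                        filter_by_group_validity(abundance, design,
                                                 min_valid = cfg$filter$min_valid))
  logged <- run_stage("preprocess", log10_transform(filtered))
  imp <- run_stage("preprocess", impute_left_censored(
    logged,
    sweeps = cfg$impute$sweeps, ridge_lambda = cfg$impute$ridge_lambda,
    n_predictors = cfg$impute$n_predictors,
    average_last = cfg$impute$average_last,
    seed = derive_seed(seed, "impute")
  ))
  imputed <- imp$table
  write_tsv(data.frame(sample_id = rownames(imputed$values),
                       as.data.frame(imputed$values), check.names = FALSE),
            file.path(outdir, "imputed_matrix.tsv"))
  manifest$stages$preprocess <- list(
    min_valid = cfg$filter$min_valid,
    n_proteins_in = ncol(abundance$values),
    n_proteins_retained = ncol(filtered$values),
    impute = cfg$impute[c("sweeps", "ridge_lambda", "n_predictors",
                          "average_last")],
    impute_sweeps_run = imp$sweeps_run,
    seed = derive_seed(seed, "impute")
  )
  note("preprocess", sprintf("retained %d/%d proteins; %d imputation sweeps",
                             ncol(filtered$values), ncol(abundance$values),
                             imp$sweeps_run))

  ## ---- univariate ---------------------------------------------------------
  kw <- run_stage("univariate", kruskal_wallis_screen(imputed, design))
  dunn <- run_stage("univariate", dunn_posthoc(
    imputed, design, kw = kw,
    candidate_alpha = cfg$univariate$candidate_alpha,
    family = cfg$univariate$dunn_family
  ))
  write_tsv(kw, file.path(outdir, "univariate_kw.tsv"))
  ann_kw <- annotation$keyword[match(dunn$protein_id, annotation$protein_id)]
  dunn_out <- cbind(dunn[1], keyword = ifelse(is.na(ann_kw), "unannotated", ann_kw),
                    dunn[-1])
  write_tsv(dunn_out, file.path(outdir, "univariate_dunn.tsv"))
  g <- design_groups(imputed, design)
  pairs <- utils::combn(levels(g), 2)
  for (q in seq_len(ncol(pairs))) {
    tr <- run_stage("univariate", abundance_trend_summary(
      imputed, design, annotation, pair = pairs[, q]))
    tag <- gsub("[^A-Za-z0-9]+", "", paste(pairs[, q], collapse = "_vs_"))
    write_tsv(tr$per_protein,
              file.path(outdir, sprintf("volcano_%02d_%s.tsv", q, tag)))
  }
  manifest$stages$univariate <- list(
    candidate_alpha = cfg$univariate$candidate_alpha,
    dunn_family = cfg$univariate$dunn_family,
    n_candidates = length(unique(dunn$protein_id)),
    n_significant_pairs = sum(dunn$p_adj < 0.05)
  )
  note("univariate", sprintf("%d candidate proteins, %d significant pairs",
                             length(unique(dunn$protein_id)),
                             sum(dunn$p_adj < 0.05)))

  ## ---- pca ----------------------------------------------------------------
  scaled <- run_stage("pca", scale_unit_variance(imputed))
  pca <- run_stage("pca", pca_explore(
    scaled, design,
    n_components = min(cfg$pca$n_components,
                       nrow(scaled$values), ncol(scaled$values))))
  write_tsv(pca$scores, file.path(outdir, "pca_scores.tsv"))
  write_tsv(data.frame(protein_id = rownames(pca$loadings),
                       as.data.frame(pca$loadings), check.names = FALSE),
            file.path(outdir, "pca_loadings.tsv"))
  manifest$stages$pca <- list(
    n_components = length(pca$variance_explained),
    variance_explained = pca$variance_explained
  )
  note("pca", sprintf("PC1 explains %.1f%%", pca$variance_explained[1]))

  ## ---- random forest ------------------------------------------------------
  if (isTRUE(cfg$rf$enabled)) {
    rows <- list()
    for (q in seq_len(ncol(pairs))) {
      a <- pairs[1, q]; b <- pairs[2, q]
      sub_rows <- g %in% c(a, b)
      sub <- abundance_table(imputed$values[sub_rows, , drop = FALSE],
                             "log10-imputed")
      rep_ <- run_stage("random_forest", rf_permutation_classifier(
        sub, factor(as.character(g[sub_rows]), levels = c(a, b)),
        n_trees = cfg$rf$n_trees,
        n_permutations = cfg$rf$n_permutations,
        seed = derive_seed(seed, paste0("rf/", a, "/", b))
      ))
      rows[[q]] <- data.frame(group1 = a, group2 = b,
                              metric = rep_$metric, value = rep_$value,
                              p = rep_$p, stringsAsFactors = FALSE)
    }
    rf_tab <- do.call(rbind, rows)
    write_tsv(rf_tab, file.path(outdir, "rf_models.tsv"))
    manifest$stages$random_forest <- list(
      n_trees = cfg$rf$n_trees, n_permutations = cfg$rf$n_permutations,
      n_models = ncol(pairs)
    )
    note("random_forest", sprintf("%d pairwise models", ncol(pairs)))
  } else {
    manifest$stages$random_forest <- list(enabled = FALSE)
    note("random_forest", "disabled")
  }

  ## ---- network ------------------------------------------------------------
  networks <- NULL
  candidates <- NULL
  if (isTRUE(cfg$network$enabled)) {
    gm <- group_matrices(imputed, design)
    networks <- list()
    chis <- list()
    for (lv in names(gm)) {
      r <- run_stage("network", spearman_matrix(gm[[lv]], warn_constant = FALSE))
      ep <- run_stage("network", estimate_edge_probabilities(
        gm[[lv]], n_iterations = cfg$network$n_iterations,
        subsample_fraction = cfg$network$subsample_fraction,
        keep_fraction = cfg$network$keep_fraction,
        seed = derive_seed(seed, paste0("pclrc/", lv))
      ))
      net <- run_stage("network", build_network(r, ep, tau = cfg$network$tau))
      networks[[lv]] <- net
      chis[[lv]] <- connectivity(net)
      tag <- gsub("[^A-Za-z0-9]+", "", lv)
      write_edge_list(net, ep, file.path(outdir, sprintf("edges_%s.tsv", tag)))
    }
    write_tsv(data.frame(protein_id = names(chis[[1]]),
                         as.data.frame(chis, check.names = FALSE),
                         check.names = FALSE),
              file.path(outdir, "connectivity.tsv"))
    ref <- cfg$network$reference_group
    others <- setdiff(names(chis), ref)
    deltas <- lapply(stats::setNames(others, others), function(lv) {
      differential_connectivity(chis[[lv]], chis[[ref]])
    })
    dc <- data.frame(protein_id = names(chis[[1]]),
                     as.data.frame(lapply(deltas, unname),
                                   check.names = FALSE),
                     check.names = FALSE)
    if (cfg$network$dc_permutations >= 19) {
      for (lv in others) {
        dp <- run_stage("network", dc_permutation_pvalues(
          gm[[lv]], gm[[ref]],
          n_permutations = cfg$network$dc_permutations,
          n_iterations = cfg$network$dc_iterations,
          subsample_fraction = cfg$network$subsample_fraction,
          keep_fraction = cfg$network$keep_fraction,
          tau = cfg$network$tau,
          seed = derive_seed(seed, paste0("dc/", lv))
        ))
        dc[[paste0(lv, ".p_adj")]] <- dp$p_adj
      }
    }
    write_tsv(dc, file.path(outdir, "differential_connectivity.tsv"))
    candidates <- run_stage("network", select_candidates(
      deltas, delta_threshold = cfg$network$delta_threshold))
    write_tsv(
      data.frame(
        comparison = rep(names(candidates$selected),
                         lengths(candidates$selected)),
        protein_id = unlist(candidates$selected, use.names = FALSE),
        stringsAsFactors = FALSE
      ),
      file.path(outdir, "dc_candidates.tsv")
    )
    manifest$stages$network <- list(
      n_iterations = cfg$network$n_iterations,
      subsample_fraction = cfg$network$subsample_fraction,
      keep_fraction = cfg$network$keep_fraction,
      tau = cfg$network$tau,
      delta_threshold = cfg$network$delta_threshold,
      reference_group = ref,
      dc_permutations = cfg$network$dc_permutations,
      n_candidates = lengths(candidates$selected),
      n_shared = length(candidates$intersection),
      seeds = lapply(stats::setNames(names(gm), names(gm)), function(lv) {
        derive_seed(seed, paste0("pclrc/", lv))
      })
    )
    note("network", sprintf("candidates per comparison: %s; shared: %d",
                            paste(lengths(candidates$selected), collapse = "/"),
                            length(candidates$intersection)))
  } else {
    manifest$stages$network <- list(enabled = FALSE)
    note("network", "disabled")
  }

  ## ---- covsca -------------------------------------------------------------
  if (isTRUE(cfg$covsca$enabled) && !is.null(networks)) {
    # Consumes the PCLRC adjacency with absolute weights and zero diagonal.
    S <- lapply(networks, function(w) {
      w <- abs(unclass(w))
      diag(w) <- 0
      w
    })
    model <- run_stage("covsca", fit_covsca(
      S, L = cfg$covsca$L, n_starts = cfg$covsca$n_starts,
      max_iter = cfg$covsca$max_iter, tol = cfg$covsca$tol,
      seed = derive_seed(seed, "covsca")
    ))
    sel <- run_stage("covsca", loading_selection(model))
    write_tsv(data.frame(group = rownames(model$weights),
                         as.data.frame(model$weights)),
              file.path(outdir, "covsca_scores.tsv"))
    write_tsv(sel, file.path(outdir, "covsca_loadings.tsv"))
    jsonlite::write_json(
      list(weights = model$weights, gof = model$gof,
           converged = model$converged, n_starts = model$n_starts,
           ranks = model$ranks),
      file.path(outdir, "covsca_model.json"), digits = NA, auto_unbox = TRUE
    )
    manifest$stages$covsca <- list(
      L = cfg$covsca$L, n_starts = cfg$covsca$n_starts,
      gof = model$gof, seed = derive_seed(seed, "covsca")
    )
    note("covsca", sprintf("GOF %.1f%%", model$gof))
  } else {
    manifest$stages$covsca <- list(enabled = FALSE)
    note("covsca", "disabled")
  }

  ## ---- enrichment ---------------------------------------------------------
  if (isTRUE(cfg$enrichment$enabled) && !is.null(candidates) &&
      nrow(annotation) > 0) {
    enr <- run_stage("enrichment", overrepresentation_test(
      candidates$intersection, protein_ids(imputed), annotation))
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    manifest$stages$enrichment <- list(
      n_target = length(candidates$intersection),
      n_terms = nrow(enr),
      n_significant = sum(enr$p_adj < 0.05)
    )
    note("enrichment", sprintf("%d terms, %d significant",
                               nrow(enr), sum(enr$p_adj < 0.05)))
  } else {
    manifest$stages$enrichment <- list(enabled = FALSE)
    note("enrichment", "disabled")
  }

  manifest$parameters <- cfg
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  invisible(manifest)
}
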