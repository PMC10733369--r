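#' Pipeline configuration
#'
#' Bundles the configuration of every analysis stage. Exactly one cohort
#' source is used: a [cohort_config()] for a synthetic cohort, or a path to
#' a cohort CSV in the [write_cohort()] schema. The global `seed`
#' deterministically reseeds every stochastic stage (generator, map
#' training, augmentation, cross-validation).
#'
#' @param cohort A [cohort_config()] or a CSV file path.
#' @param esom An [esom_config()].
#' @param plan An [augmentation_plan()].
#' @param scheme A [cv_scheme()].
#' @param out_dir Output directory for the stage reports.
#' @param seed Global integer seed.
#' @param thresholds Stage thresholds, see [stage_thresholds()].
#' @param importance_repeats Permutation-importance repeats for the
#'   remission-vs-active item selection.
#' @param evaluate_clusters Run the (slower) nested cross-validated
#'   single-feature evaluation per cluster in the cluster-membership stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            esom = esom_config(),
                            plan = augmentation_plan(),
                            scheme = cv_scheme(),
                            out_dir = tempfile("das28map_run_"),
                            seed = 42L,
                            thresholds = stage_thresholds(),
                            importance_repeats = 50,
                            evaluate_clusters = FALSE) {
  seed <- as.integer(seed)
  if (inherits(cohort, "cohort_config")) cohort$seed <- seed
  esom$seed <- seed + 1L
  plan$seed <- seed + 2L
  scheme$seed <- seed + 3L
  structure(list(cohort = cohort, esom = esom, plan = plan, scheme = scheme,
                 out_dir = out_dir, seed = seed, thresholds = thresholds,
                 importance_repeats = importance_repeats,
                 evaluate_clusters = evaluate_clusters),
            class = "pipeline_config")
}

#' Validate a cohort table against the expected schema
#'
#' Checks the 28 + 28 joint-flag columns, value ranges (flags binary, CRP
#' nonnegative, GH within 0-100) and missingness.
#'
#' @param x Cohort data frame or CSV path.
#' @return List with `valid` (logical), `violations` (data frame
#'   `column, problem, n`), `n_rows`, `n_cols`.
#' @export
validate_cohort <- function(x) {
  cohort <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("patient_id", tender_columns(), swollen_columns(), "crp_mg_l", "gh_mm")
  viol <- list()
  add <- function(column, problem, n) {
    viol[[length(viol) + 1L]] <<- data.frame(column = column, problem = problem,
                                             n = n, stringsAsFactors = FALSE)
  }
  for (col in setdiff(need, names(cohort))) add(col, "missing column", nrow(cohort))
  for (col in intersect(c(tender_columns(), swollen_columns()), names(cohort))) {
    bad <- sum(!cohort[[col]] %in% c(0, 1))
    if (bad > 0) add(col, "flag not 0/1", bad)
  }
  if ("crp_mg_l" %in% names(cohort)) {
    bad <- sum(is.na(cohort$crp_mg_l) | cohort$crp_mg_l < 0)
    if (bad > 0) add("crp_mg_l", "missing or negative", bad)
  }
  if ("gh_mm" %in% names(cohort)) {
    bad <- sum(is.na(cohort$gh_mm) | cohort$gh_mm < 0 | cohort$gh_mm > 100)
    if (bad > 0) add("gh_mm", "missing or outside 0-100", bad)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(column = character(0), problem = character(0), n = integer(0))
  list(valid = nrow(violations) == 0, violations = violations,
       n_rows = nrow(cohort), n_cols = ncol(cohort))
}

#' Run the full analysis pipeline
#'
#' Executes the eight analysis stages in order — scoring/staging, PCA, ESOM
#' training with U-/P-/U*-matrices, cluster and outlier extraction,
#' generative cluster equalization, remission-vs-active item selection on
#' the 58-item representation, cluster-membership attribution on the four
#' components, and association statistics — writing each stage's interface
#' files under `config$out_dir` plus a run manifest with seeds, timings and
#' a config hash.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "das28map",
                   version = as.character(utils::packageVersion("das28map")),
                   seed = config$seed, stages = list())
  t_all <- Sys.time()
  results <- list()
  stage_names <- character(0)
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "completed",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    results[[name]] <<- res
    res
  }

  # -- 1: cohort + scoring/staging ------------------------------------------
  score_tab <- run_stage("score_stage", function() {
    cohort <- if (inherits(config$cohort, "cohort_config")) {
      inject_outliers(generate_cohort(config$cohort), config$cohort)
    } else {
      read_cohort(config$cohort)
    }
    v <- validate_cohort(cohort)
    if (!v$valid) stop("cohort failed schema validation")
    tab <- score_cohort(cohort, thresholds = config$thresholds)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    utils::write.csv(tab, file.path(config$out_dir, "scores.csv"),
                     row.names = FALSE)
    list(cohort = cohort, scores = tab)
  })
  cohort <- score_tab$cohort
  comp4 <- as.matrix(score_tab$scores[, c("tjc28", "sjc28", "crp", "gh")])

  # -- 2: PCA ----------------------------------------------------------------
  run_stage("pca", function() {
    pca <- pca_project(comp4)
    jsonlite::write_json(
      list(eigenvalues = pca$eigenvalues,
           variance_explained = pca$variance_explained,
           contributions = as.data.frame(pca$contributions)),
      file.path(config$out_dir, "pca.json"), auto_unbox = TRUE, digits = NA)
    pca
  })

  # -- 3: ESOM + structure matrices -----------------------------------------
  esom_res <- run_stage("esom", function() {
    sc <- scale_0_100(comp4)
    model <- train_esom(sc$scaled, config$esom, input_scaling = sc$ranges)
    r <- pareto_radius(sc$scaled)
    u <- u_matrix(model)
    p <- p_matrix(model, sc$scaled, r)
    ustar <- u_star_matrix(u, p)
    for (nm in c("u", "p", "ustar")) {
      mat <- matrix(get(nm), config$esom$rows, config$esom$cols, byrow = TRUE)
      utils::write.table(mat, file.path(config$out_dir, paste0(nm, "_matrix.csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    jsonlite::write_json(
      list(rows = config$esom$rows, cols = config$esom$cols,
           toroidal = config$esom$toroidal, epochs = config$esom$epochs,
           lr = c(config$esom$lr_start, config$esom$lr_end),
           pareto_radius = r, seed = config$esom$seed),
      file.path(config$out_dir, "esom.json"), auto_unbox = TRUE, digits = NA)
    list(model = model, scaled = sc, radius = r, u = u, p = p, ustar = ustar)
  })

  # -- 4: clusters / outliers ------------------------------------------------
  cluster_res <- run_stage("clusters", function() {
    bmus <- assign_bmus(esom_res$model, esom_res$scaled$scaled)
    assignment <- extract_clusters(esom_res$ustar, bmus, esom_res$model)
    assoc <- tryCatch(
      cluster_stage_association(assignment, score_tab$scores$stage),
      error = function(e) list(error = conditionMessage(e)))
    utils::write.csv(
      data.frame(patient_id = cohort$patient_id,
                 cluster = assignment$cluster,
                 is_outlier = assignment$is_outlier),
      file.path(config$out_dir, "clusters.csv"), row.names = FALSE)
    list(bmus = bmus, assignment = assignment, stage_association = assoc)
  })

  # -- 5: generative augmentation -------------------------------------------
  augment_res <- run_stage("augment", function() {
    eq <- equalize_clusters(esom_res$model, esom_res$p,
                            cluster_res$assignment, esom_res$scaled$scaled,
                            config$plan)
    aug <- as.data.frame(eq$data)
    aug$cluster <- eq$cluster
    aug$is_synthetic <- eq$is_synthetic
    aug$seed_patient_id <- NA_character_
    if (!is.null(eq$provenance)) {
      aug$seed_patient_id[eq$is_synthetic] <- cohort$patient_id[eq$provenance$seed_row]
    }
    utils::write.csv(aug, file.path(config$out_dir, "augmented.csv"),
                     row.names = FALSE)
    eq
  })

  # -- 6: remission-vs-active item selection (d = 58) -----------------------
  selection_res <- run_stage("select_remission", function() {
    items <- expand_items(cohort)
    y <- factor(ifelse(score_tab$scores$stage == "remission",
                       "remission", "active"),
                levels = c("remission", "active"))
    split <- split_holdout(y, config$scheme)
    model <- tune_and_train(items[split$train, ], y[split$train], config$scheme)
    imp <- permutation_importance(model, items[split$train, ], y[split$train],
                                  n_repeats = config$importance_repeats,
                                  seed = config$scheme$seed)
    abc <- cabc(setNames(imp$mean_importance, imp$feature))
    perf_reduced <- nested_cv_evaluate(items, y, features = abc$A,
                                       scheme = config$scheme)
    perf_permuted <- nested_cv_evaluate(items, y, features = abc$A,
                                        scheme = config$scheme,
                                        permute_features = TRUE)
    imp$abc_set <- ifelse(imp$feature %in% abc$A, "A",
                          ifelse(imp$feature %in% abc$B, "B", "C"))
    utils::write.csv(imp, file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(reduced_features = abc$A,
           reduced = list(median = perf_reduced$median,
                          ci = as.data.frame(perf_reduced$ci),
                          runs = perf_reduced$runs),
           permuted_control = list(median = perf_permuted$median,
                                   ci = as.data.frame(perf_permuted$ci),
                                   runs = perf_permuted$runs),
           outer_repeats = config$scheme$outer_repeats,
           inner_repeats = config$scheme$inner_repeats),
      file.path(config$out_dir, "performance.json"),
      auto_unbox = TRUE, digits = NA)
    list(importance = imp, abc = abc, reduced = perf_reduced,
         permuted = perf_permuted)
  })

  # -- 7: cluster-membership attribution (d = 4) ----------------------------
  run_stage("cluster_membership", function() {
    if (length(unique(augment_res$cluster)) < 2) {
      return(list(note = "single cluster: no membership attribution possible"))
    }
    cluster_membership_importance(
      augment_res$data, augment_res$cluster, config$scheme,
      n_repeats = config$importance_repeats,
      evaluate = config$evaluate_clusters)
  })

  # -- 8: association statistics --------------------------------------------
  run_stage("associations", function() {
    stages <- score_tab$scores$stage
    quart <- apply(comp4, 2, quartile_rescale)
    tests <- list()
    for (j in colnames(comp4)) {
      tab <- table(quartile = quart[, j], stage = droplevels(stages))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      tests[[paste0("stage_vs_", j, "_quartile")]] <-
        if (nrow(tab) >= 2 && ncol(tab) >= 2) {
          ct <- chi2_test(tab)
          list(statistic = ct$statistic, df = ct$df, p.value = ct$p.value,
               residuals = as.data.frame(as.matrix(ct$residuals)))
        } else list(error = "degenerate table")
    }
    if (any(!is.na(cohort$drug_class))) {
      tab <- table(drug = cohort$drug_class, stage = droplevels(stages))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) >= 2 && ncol(tab) >= 2) {
        ct <- chi2_test(tab)
        tests$stage_vs_drug_class <- list(statistic = ct$statistic, df = ct$df,
                                          p.value = ct$p.value)
      }
    }
    if (any(!is.na(cohort$therapy_start_days))) {
      groups <- split(cohort$therapy_start_days[!is.na(cohort$therapy_start_days)],
                      droplevels(stages[!is.na(cohort$therapy_start_days)]))
      if (length(groups) >= 2) {
        tests$therapy_start_by_stage <- kruskal_wallis(groups)
      }
    }
    jsonlite::write_json(tests, file.path(config$out_dir, "associations.json"),
                         auto_unbox = TRUE, digits = NA)
    tests
  })

  # -- manifest --------------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(
    list(seed = config$seed,
         esom = unclass(config$esom), scheme = unclass(config$scheme),
         thresholds = as.list(config$thresholds)),
    cfg_path, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
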