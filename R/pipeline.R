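#' Run one two-group disease model end to end
#'
#' Orchestrates a full model run for one pair of groups: take (or build)
#' per-subject cell tables, assign cells to leaf subtypes (graph clustering
#' plus annotation, or ground-truth labels when available), build and
#' normalise the immune feature matrix across the modelled subjects, rank
#' features by Spearman association and select the leading block at the
#' cumulative -log10(p) inflection, and fit the prior-weighted elastic net
#' with repeated cross-validation. All stage outputs and a run manifest are
#' written to `output_dir`.
#'
#' @param cohort A `synthetic_cohort`, or a list with `cells` (list of
#'   [cell_table()]) and `meta` (subject metadata).
#' @param pair Two group labels, case first (e.g. `c("AD", "HC")`).
#' @param taxonomy A `subtype_taxonomy`; defaults to the cohort's (synthetic
#'   cohorts carry one) or [default_taxonomy()].
#' @param use_oracle Use ground-truth cell labels instead of clustering
#'   (synthetic cohorts only).
#' @param cluster_k,cluster_resolution kNN-graph clustering parameters.
#' @param alpha,phi,prior,n_repeats,n_folds Passed to [ien()].
#' @param seed Mandatory seed driving clustering, folds and all RNG.
#' @param output_dir Directory for stage outputs; `NULL` skips writing.
#' @return A list of class `model_pair_run`: `feature_matrix`, `ranking`,
#'   `model` (the `ien` fit), `meta` (modelled subjects), `manifest`.
#' @export
run_model_pair <- function(cohort, pair, taxonomy = NULL,
                           use_oracle = inherits(cohort, "synthetic_cohort"),
                           cluster_k = 30, cluster_resolution = 1,
                           alpha = 0.5, phi = 0, prior = NULL,
                           n_repeats = 100, n_folds = 10, seed,
                           output_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  t0 <- Sys.time()
  stopifnot(length(pair) == 2)
  meta <- cohort$meta
  if (!all(pair %in% meta$group))
    stop("model pair must be a subset of the metadata groups")
  taxonomy <- taxonomy %||% cohort$taxonomy %||% default_taxonomy()

  if (use_oracle) {
    assignment <- oracle_assign(cohort)
  } else {
    pooled <- pool_cells(cohort$cells)
    assignment <- cluster_cells(pooled, k = cluster_k,
                                resolution = cluster_resolution,
                                seed = derive_seed(seed, 101))
    assignment <- annotate_clusters(assignment, taxonomy)
  }
  pooled <- pool_cells(cohort$cells)

  keep <- meta$group %in% pair
  subjects <- meta$subject_id[keep]
  # features are built, and normalised, over the modelled subjects only
  keep_cells <- assignment$subject %in% subjects
  sub_assignment <- assignment
  sub_assignment$cluster <- assignment$cluster[keep_cells]
  sub_assignment$cell_leaf <- assignment$cell_leaf[keep_cells]
  sub_assignment$subject <- assignment$subject[keep_cells]
  fm <- featurize(sub_assignment, pooled$matrix[keep_cells, , drop = FALSE],
                  taxonomy, subjects = subjects)

  labels <- factor(meta$group[keep], levels = pair)
  ranking <- suppressWarnings(rank_features(fm, labels))
  ranking <- select_inflection(ranking)
  sel <- ranking$feature[ranking$selected]
  if (length(sel) < 2) sel <- ranking$feature[seq_len(min(5, nrow(ranking)))]
  model <- ien(fm$values[, sel, drop = FALSE], labels, alpha = alpha,
               prior = prior, phi = phi, n_repeats = n_repeats,
               n_folds = n_folds, seed = derive_seed(seed, 202))

  manifest <- list(pair = pair, n_subjects = length(subjects),
                   n_features = ncol(fm$values),
                   n_selected = length(sel),
                   use_oracle = use_oracle, seed = seed,
                   hyperparameters = model$hyperparameters,
                   auc = model$auc, mwu_p = model$mwu_p,
                   package_version = as.character(
                     utils::packageVersion("cytoien")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  out <- structure(list(feature_matrix = fm, ranking = ranking,
                        model = model, meta = meta[keep, , drop = FALSE],
                        manifest = manifest),
                   class = "model_pair_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(fm, file.path(output_dir, "feature_matrix.csv"))
    write.csv(as.data.frame(ranking),
              file.path(output_dir, "feature_ranking.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(manifest = manifest,
           predictions = as.list(model$predictions),
           auc_per_repeat = model$auc_per_repeat,
           coef_frequency = as.list(model$coef_frequency[
             model$coef_frequency > 0])),
      file.path(output_dir, "model_result.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.model_pair_run <- function(x, ...) {
  cat("model_pair_run:", paste(x$manifest$pair, collapse = " vs "), "-",
      x$manifest$n_subjects, "subjects,", x$manifest$n_features,
      "features,", x$manifest$n_selected, "selected\n")
  print(x$model)
  invisible(x)
}

#' Compare model AUC with scalar plasma biomarkers
#'
#' Tabulates the cross-validated model AUC against the univariate ROC AUC
#' of each scalar biomarker and of the biomarker pair combined by a
#' two-feature logistic score. Missing biomarker columns are omitted with a
#' warning.
#'
#' @param run A `model_pair_run` from [run_model_pair()].
#' @param biomarkers Biomarker column names in the metadata.
#' @return Data frame `score`, `auc`.
#' @export
compare_biomarkers <- function(run, biomarkers = c("pTau181", "NFL")) {
  stopifnot(inherits(run, "model_pair_run"))
  meta <- run$meta
  labels <- factor(meta$group, levels = run$manifest$pair)
  out <- data.frame(score = "iEN", auc = run$model$auc)
  present <- biomarkers[biomarkers %in% names(meta)]
  absent <- setdiff(biomarkers, present)
  if (length(absent))
    warning("biomarker column(s) missing, omitted: ",
            paste(absent, collapse = ", "))
  for (b in present)
    out <- rbind(out, data.frame(score = b,
                                 auc = univariate_roc(meta, b, labels)$auc))
  if (length(present) == 2)
    out <- rbind(out, data.frame(
      score = paste(present, collapse = "+"),
      auc = univariate_roc(meta, present, labels)$auc))
  out
}
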