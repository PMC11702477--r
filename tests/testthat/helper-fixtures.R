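# shared fixture builders; everything is generated in code at test time

# small two-group cohort on the default taxonomy
small_cohort <- function(n_per_group = 8, n_cells = 200, seed = 11,
                         groups = c("AD", "HC"), ...) {
  cfg <- cohort_config(
    n_subjects_per_group = setNames(rep(n_per_group, length(groups)), groups),
    n_cells_per_subject = n_cells, seed = seed, ...)
  generate_cohort(cfg, default_taxonomy())
}

# the five leaf/marker pairs used for planted-effect experiments
planted_pairs <- function() {
  list(subtypes = c("M01", "T01", "NK02", "B02", "T05"),
       markers = c("IKBa", "pSTAT3", "pERK1_2", "pS6", "pNFkB"),
       features = c("M01__IKBa", "T01__pSTAT3", "NK02__pERK1_2",
                    "B02__pS6", "T05__pNFkB"))
}

# feature matrix of a cohort via ground-truth labels
cohort_features <- function(cohort) {
  featurize(oracle_assign(cohort), pool_cells(cohort$cells),
            cohort$taxonomy, subjects = cohort$meta$subject_id)
}

# binary labels of a cohort as a factor, case level first
cohort_labels <- function(cohort, pair) {
  factor(cohort$meta$group, levels = pair)
}

# a tiny three-leaf taxonomy written to a temp YAML file
tiny_taxonomy_yaml <- function(path = tempfile(fileext = ".yaml"),
                               drop_parent = FALSE) {
  panel <- c("m1", "m2", "m3")
  leaves <- list(
    list(name = "L1", parent = "A", signature = list(4, 0.5, 0.5)),
    list(name = "L2", parent = if (drop_parent) "nosuch" else "A",
         signature = list(0.5, 4, 0.5)),
    list(name = "L3", parent = "B", signature = list(0.5, 0.5, 4)))
  yaml::write_yaml(list(panel = as.list(panel),
                        signature_markers = as.list(panel),
                        feature_markers = as.list(panel),
                        tier1 = list("A", "B"),
                        tier2 = list(),
                        tier3 = leaves),
                   path)
  path
}

# Gaussian blob mixture with known labels for clustering tests
blob_data <- function(n_per = 200, d = 5, sep = 10, sd = 1, seed = 5) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(sep, rep(0, d - 1)), c(0, sep, rep(0, d - 2)))
  X <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)))
  colnames(X) <- paste0("m", seq_len(d))
  list(x = X, labels = rep(1:3, each = n_per))
}
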