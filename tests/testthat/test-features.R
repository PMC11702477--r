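test_that("feature count identity holds for default and custom taxonomies", {
  coh <- small_cohort(n_per_group = 3, n_cells = 100, seed = 23)
  fm <- cohort_features(coh)
  expect_equal(ncol(fm$values), 39 + 41 * 29)   # 1228
  expect_equal(sum(fm$features$kind == "abundance"), 39)
  expect_equal(sum(fm$features$kind == "marker_summary"), 41 * 29)

  tax <- load_taxonomy(tiny_taxonomy_yaml())
  n_expected <- length(tax$tier1) + nrow(tax$tier2) + nrow(tax$tier3) +
    length(tax$feature_markers) * nrow(tax$tier3)
  # brute-force recount straight from the descriptor table
  asg <- structure(list(cluster = rep(1:3, each = 10),
                        cell_leaf = rep(c("L1", "L2", "L3"), each = 10),
                        subject = rep(c("a", "b"), 15)),
                   class = "cluster_assignment")
  pooled <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, tax$panel))
  fm2 <- featurize(asg, pooled, tax, subjects = c("a", "b"))
  expect_equal(ncol(fm2$values), n_expected)
  expect_equal(nrow(fm2$features), n_expected)
})

test_that("abundance fractions follow the worked arithmetic example", {
  tax <- default_taxonomy()
  labs <- rep(c("T01", "M01", "NK02", "B02"), c(53, 21, 18, 8))
  asg <- structure(list(cluster = seq_along(labs), cell_leaf = labs,
                        subject = rep("s1", 100)),
                   class = "cluster_assignment")
  ab <- compute_abundances(asg, tax, "s1")
  expect_equal(ab["s1", "T"], 0.53)
  expect_equal(ab["s1", "Myeloid"], 0.21)
  expect_equal(ab["s1", "NK"], 0.18)
  expect_equal(ab["s1", "B"], 0.08)
  expect_equal(ab["s1", "T01"], 0.53)   # only T leaf present
  # all cells in one leaf: the leaf and its ancestors are 1, others 0
  asg1 <- structure(list(cluster = 1:10, cell_leaf = rep("T03", 10),
                         subject = rep("s1", 10)),
                    class = "cluster_assignment")
  ab1 <- compute_abundances(asg1, tax, "s1")
  expect_equal(unname(ab1["s1", c("T03", "CD4 TCM", "T")]), c(1, 1, 1))
  expect_equal(sum(ab1), 3)
})

test_that("tier fractions are sums over descendant leaves", {
  coh <- small_cohort(n_per_group = 4, n_cells = 150, seed = 29)
  ab <- compute_abundances(oracle_assign(coh), coh$taxonomy,
                           coh$meta$subject_id)
  tax <- coh$taxonomy
  for (g in c(tax$tier1, tax$tier2$name)) {
    lv <- descendant_leaves(tax, g)
    expect_equal(ab[, g], rowSums(ab[, lv, drop = FALSE]), tolerance = 1e-9)
  }
  expect_equal(unname(rowSums(ab[, tax$tier1])),
               rep(1, nrow(ab)), tolerance = 1e-9)
  # every leaf bounded by its tier-1 ancestor
  for (i in seq_len(nrow(tax$tier3)))
    expect_true(all(ab[, tax$tier3$name[i]] <=
                      ab[, tax$tier3$tier1[i]] + 1e-9))
})

test_that("marker summaries equal leaf signatures in the noiseless case", {
  cfg <- cohort_config(n_subjects_per_group = c(AD = 2, HC = 2),
                       n_cells_per_subject = 200, noise_sd = 0,
                       subject_sd = 0, seed = 37)
  coh <- generate_cohort(cfg)
  tax <- coh$taxonomy
  ms <- compute_marker_summaries(oracle_assign(coh), pool_cells(coh$cells),
                                 tax, coh$meta$subject_id)
  present <- unique(coh$truth$cell_labels[[1]])
  for (leaf in present[1:5])
    expect_equal(unname(ms[1, paste(leaf, tax$feature_markers,
                                    sep = "__")]),
                 unname(tax$signatures[leaf, tax$feature_markers]),
                 tolerance = 1e-12)
})

test_that("empty leaves are imputed with the cohort median and flagged", {
  tax <- load_taxonomy(tiny_taxonomy_yaml())
  labs <- c(rep("L1", 4), rep("L2", 4), rep("L1", 4), rep("L2", 3), "L3")
  subj <- rep(c("a", "b"), each = 8)
  pooled <- matrix(seq_len(48), 16, 3, dimnames = list(NULL, tax$panel))
  asg <- structure(list(cluster = seq_along(labs), cell_leaf = labs,
                        subject = subj),
                   class = "cluster_assignment")
  ms <- compute_marker_summaries(asg, pooled, tax, c("a", "b"))
  imp <- attr(ms, "imputed")
  expect_true(all(imp["a", paste("L3", tax$panel, sep = "__")]))
  # subject a's L3 summaries imputed with the only other value (cohort median)
  expect_equal(ms["a", "L3__m1"], ms["b", "L3__m1"])
  # single-cell leaf: median is that cell's value
  expect_equal(unname(ms["b", "L3__m1"]), unname(pooled[16, "m1"]))
})

test_that("z-scoring is exact and invertible", {
  coh <- small_cohort(n_per_group = 4, n_cells = 120, seed = 43)
  asg <- oracle_assign(coh)
  pooled <- pool_cells(coh$cells)
  ab <- compute_abundances(asg, coh$taxonomy, coh$meta$subject_id)
  ms <- compute_marker_summaries(asg, pooled, coh$taxonomy,
                                 coh$meta$subject_id)
  fm <- build_feature_matrix(ab, ms, coh$taxonomy)
  ok <- !fm$degenerate
  mu <- colMeans(fm$values[, ok]); s <- apply(fm$values[, ok], 2, sd)
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(s - 1)), 1e-9)
  raw <- sweep(sweep(fm$values, 2, fm$scale, "*"), 2, fm$center, "+")
  expect_equal(unname(raw[, colnames(ab)]), unname(ab), tolerance = 1e-9)
})

test_that("feature matrix CSV + sidecar round trip is faithful", {
  coh <- small_cohort(n_per_group = 3, n_cells = 80, seed = 47)
  fm <- cohort_features(coh)
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$features$name, fm$features$name)
  expect_equal(back$center, unname(fm$center), tolerance = 1e-12)
})
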