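test_that("generator is deterministic and conserves cell counts", {
  coh1 <- small_cohort(n_per_group = 4, n_cells = 150, seed = 21)
  coh2 <- small_cohort(n_per_group = 4, n_cells = 150, seed = 21)
  expect_identical(coh1$cells[[1]]$matrix, coh2$cells[[1]]$matrix)
  expect_identical(coh1$truth$leaf_fractions, coh2$truth$leaf_fractions)
  for (id in coh1$meta$subject_id) {
    expect_equal(nrow(coh1$cells[[id]]$matrix), 150)
    expect_length(coh1$truth$cell_labels[[id]], 150)
  }
  expect_equal(unname(rowSums(coh1$truth$leaf_fractions)),
               rep(1, nrow(coh1$meta)), tolerance = 1e-9)
})

test_that("group sizes follow the configured design", {
  cfg <- cohort_config(n_subjects_per_group = c(AD = 14, DLB = 25, HC = 18),
                       n_cells_per_subject = 30, seed = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh$cells, 57)
  expect_equal(as.vector(table(factor(coh$meta$group,
                                      c("AD", "DLB", "HC")))),
               c(14, 25, 18))
  # both sexes present per group (alternating assignment)
  expect_true(all(table(coh$meta$group, coh$meta$sex) > 0))
})

test_that("planted marker effect is exact when noise is off", {
  delta <- 0.7
  cfg <- cohort_config(n_subjects_per_group = c(AD = 3, HC = 3),
                       n_cells_per_subject = 100, noise_sd = 0,
                       subject_sd = 0,
                       marker_effects = data.frame(
                         group = "AD", subtype = "M01", marker = "IKBa",
                         shift = delta),
                       seed = 31)
  coh <- generate_cohort(cfg)
  vals <- function(g) {
    ids <- coh$meta$subject_id[coh$meta$group == g]
    unlist(lapply(ids, function(id) {
      lab <- coh$truth$cell_labels[[id]]
      coh$cells[[id]]$matrix[lab == "M01", "IKBa"]
    }))
  }
  expect_equal(mean(vals("AD")) - mean(vals("HC")), delta, tolerance = 1e-12)
  # and with zero noise every cell matches its leaf signature exactly
  tax <- default_taxonomy()
  id <- coh$meta$subject_id[coh$meta$group == "HC"][1]
  lab <- coh$truth$cell_labels[[id]]
  expect_equal(coh$cells[[id]]$matrix,
               unname(tax$signatures[lab, , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("abundance effects shift composition and invalid configs error", {
  cfg <- cohort_config(n_subjects_per_group = c(AD = 6, HC = 6),
                       n_cells_per_subject = 500,
                       abundance_effects = data.frame(
                         group = "AD", subtype = "T", multiplier = 0.5),
                       seed = 7)
  coh <- generate_cohort(cfg)
  gt <- coh$truth$group_fractions
  t_ad <- mean(gt[coh$meta$group == "AD", "T"])
  t_hc <- mean(gt[coh$meta$group == "HC", "T"])
  expect_lt(t_ad, t_hc)

  bad <- cohort_config(n_subjects_per_group = c(AD = 2, HC = 2),
                       marker_effects = data.frame(
                         group = "AD", subtype = "nosuch", marker = "IKBa",
                         shift = 1),
                       seed = 1)
  expect_error(generate_cohort(bad), "nosuch")
  bad2 <- cohort_config(n_subjects_per_group = c(AD = 2, HC = 2),
                        abundance_effects = data.frame(
                          group = "AD", subtype = "T", multiplier = -1),
                        seed = 1)
  expect_error(generate_cohort(bad2), "multiplier")
})

test_that("synthetic biomarkers behave like null / separated scalars", {
  coh <- small_cohort(n_per_group = 10, n_cells = 20, seed = 41)
  meta0 <- generate_biomarkers(coh$meta, effect_size = 0,
                               case_group = "AD", seed = 1)
  labs <- cohort_labels(coh, c("AD", "HC"))
  auc0 <- univariate_roc(meta0, "pTau181", labs)$auc
  expect_gt(auc0, 0.2); expect_lt(auc0, 0.8)
  # huge effect separates completely
  meta10 <- generate_biomarkers(coh$meta, effect_size = 10,
                                case_group = "AD", seed = 2)
  expect_equal(univariate_roc(meta10, "pTau181", labs)$auc, 1.0)
  # ROC symmetry under sign flip
  m <- meta10
  m$neg <- -m$pTau181
  expect_equal(univariate_roc(meta10, "pTau181", labs)$auc +
                 univariate_roc(m, "neg", labs)$auc, 1.0)
})

test_that("cohort export writes per-subject CSVs and metadata", {
  coh <- small_cohort(n_per_group = 2, n_cells = 25, seed = 5)
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "S001.csv")))
  meta <- read_subject_meta(file.path(dir, "subjects.csv"))
  expect_equal(nrow(meta), 4)
  back <- read_cells(file.path(dir, "S001.csv"), coh$taxonomy$panel)
  expect_equal(back$matrix, coh$cells[[1]]$matrix, tolerance = 1e-6,
               ignore_attr = TRUE)
})
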