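test_that("Spearman ranking matches the t-approximation oracle", {
  set.seed(51)
  n <- 20
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(1, 0), each = n / 2)
  rk <- rank_features(x, y)
  for (j in colnames(x)) {
    rho <- cor(rank(x[, j]), rank(y))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    i <- match(j, rk$feature)
    expect_equal(rk$rho[i], rho, tolerance = 1e-12)
    expect_equal(rk$p[i], p, tolerance = 1e-12)
  }
  # sorted non-decreasing in p, cumulative curve non-decreasing
  expect_true(!is.unsorted(rk$p))
  sel <- select_inflection(rk)
  expect_true(!is.unsorted(sel$cum_neg_log10_p))
})

test_that("a label-identical feature ranks first; label vs itself has rho 1", {
  set.seed(53)
  y <- rep(c(1, 0), each = 10)
  x <- cbind(exact = y, matrix(rnorm(20 * 9), 20, 9))
  colnames(x)[2:10] <- paste0("n", 1:9)
  rk <- rank_features(x, y)
  expect_equal(rk$feature[1], "exact")
  expect_equal(rk$rho[1], 1.0)
  expect_equal(min(rk$p), rk$p[1])
})

test_that("degenerate labels and zero-variance features are handled", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(rank_features(x, rep(1, 10)), "single class")
  x[, 2] <- 5
  expect_warning(rk <- rank_features(x, rep(c(1, 0), 5)), "zero-variance")
  expect_false("f2" %in% rk$feature)
})

test_that("inflection selection reproduces the worked six-value example", {
  p <- c(1e-6, 1e-5, 1e-4, 0.3, 0.35, 0.4)
  rk <- structure(data.frame(feature = paste0("f", 1:6), rho = 0.5, p = p,
                             neg_log10_p = -log10(p)),
                  class = c("feature_ranking", "data.frame"))
  out <- select_inflection(rk)
  expect_equal(out$first_diff, -log10(p))
  expect_equal(out$second_diff[1:5], diff(-log10(p)), tolerance = 1e-12)
  expect_equal(attr(out, "inflection_index"), 3L)
  expect_equal(sum(out$selected), 3)
  expect_false(attr(out, "fallback"))
})

test_that("inflection equals the brute-force breakpoint scan on random sequences", {
  set.seed(59)
  for (i in 1:100) {
    K <- sample(5:60, 1)
    p <- sort(10^(-runif(K, 0, 8)))
    rk <- structure(data.frame(feature = paste0("f", seq_len(K)),
                               rho = 0, p = p, neg_log10_p = -log10(p)),
                    class = c("feature_ranking", "data.frame"))
    out <- select_inflection(rk)
    if (attr(out, "fallback")) next
    expect_equal(attr(out, "inflection_index"), oracle_inflection(p))
  }
})

test_that("degenerate p sequences fall back to the p < 0.05 rule", {
  # all p equal: no curvature at all
  p_eq <- rep(0.2, 8)
  rk <- structure(data.frame(feature = paste0("f", 1:8), rho = 0, p = p_eq,
                             neg_log10_p = -log10(p_eq)),
                  class = c("feature_ranking", "data.frame"))
  out <- select_inflection(rk)
  expect_true(attr(out, "fallback"))
  expect_equal(sum(out$selected), 0)
  # geometric sequence: constant second difference
  p_geo <- 0.001 * 2^(0:9)
  rk2 <- structure(data.frame(feature = paste0("f", 1:10), rho = 0,
                              p = p_geo, neg_log10_p = -log10(p_geo)),
                   class = c("feature_ranking", "data.frame"))
  out2 <- select_inflection(rk2)
  expect_true(attr(out2, "fallback"))
  expect_equal(sum(out2$selected), sum(p_geo < 0.05))
  # fewer than 3 features
  rk3 <- structure(data.frame(feature = "f1", rho = 0, p = 0.01,
                              neg_log10_p = 2),
                   class = c("feature_ranking", "data.frame"))
  expect_true(attr(select_inflection(rk3), "fallback"))
})

test_that("ranking and selection are deterministic", {
  coh <- small_cohort(n_per_group = 5, n_cells = 100, seed = 61)
  fm <- cohort_features(coh)
  labs <- cohort_labels(coh, c("AD", "HC"))
  r1 <- select_inflection(suppressWarnings(rank_features(fm, labs)))
  r2 <- select_inflection(suppressWarnings(rank_features(fm, labs)))
  expect_identical(r1$feature, r2$feature)
  expect_identical(r1$selected, r2$selected)
})

test_that("sex-specific planted effects surface in the affected subgroup", {
  pp <- planted_pairs()
  cfg <- cohort_config(n_subjects_per_group = c(AD = 16, HC = 16),
                       n_cells_per_subject = 200, seed = 67)
  cfg <- plant_marker_effects(cfg, pp$subtypes[1], pp$markers[1],
                              group = "AD", effect_size = 3, sex = "M")
  coh <- generate_cohort(cfg)
  fm <- cohort_features(coh)
  parts <- sex_partitions(coh$meta, c("AD", "HC"))
  res <- suppressWarnings(subgroup_rescan(fm, coh$meta, parts,
                                          features = pp$features[1]))
  tab <- res$table
  expect_gt(tab[1, "male_case_male_ctrl"], tab[1, "female_case_female_ctrl"])
  # identical partitions give identical rankings
  parts2 <- list(a = parts[[1]], b = parts[[1]])
  res2 <- suppressWarnings(subgroup_rescan(fm, coh$meta, parts2))
  expect_equal(res2$rankings$a$p, res2$rankings$b$p)
})

test_that("undersized subgroups are skipped with a warning", {
  coh <- small_cohort(n_per_group = 6, n_cells = 60, seed = 71)
  fm <- cohort_features(coh)
  parts <- list(tiny = list(subjects = coh$meta$subject_id[1:4],
                            pair = c("AD", "HC")),
                fine = list(subjects = coh$meta$subject_id,
                            pair = c("AD", "HC")))
  expect_warning(res <- subgroup_rescan(fm, coh$meta, parts), "skipped")
  expect_named(res$rankings, "fine")
})
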