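test_that("MWU equals complete enumeration for all group sizes up to 8", {
  set.seed(149)
  for (n1 in 2:8) for (n2 in 2:8) {
    x <- rnorm(n1); y <- rnorm(n2)
    mw <- mwu_test(x, y)
    expect_equal(mw$p, oracle_mwu_enumeration(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d continuous", n1, n2))
    # and with heavy ties
    xt <- sample(1:3, n1, replace = TRUE)
    yt <- sample(1:3, n2, replace = TRUE)
    expect_equal(mwu_test(xt, yt)$p, oracle_mwu_enumeration(xt, yt),
                 tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d ties", n1, n2))
  }
})

test_that("3 vs 3 complete separation gives exact two-sided p = 0.1", {
  mw <- mwu_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(mw$p, 0.1, tolerance = 1e-12)
  expect_equal(mw$auc, 1.0)
})

test_that("tie-free mid-size MWU matches the exact null distribution", {
  set.seed(151)
  x <- rnorm(15); y <- rnorm(12)
  mw <- mwu_test(x, y)
  expect_equal(mw$method, "exact distribution")
  ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(mw$u, unname(ref$statistic), tolerance = 1e-12)
})

test_that("large-sample MWU uses the tie-corrected normal approximation", {
  set.seed(157)
  x <- sample(1:5, 60, replace = TRUE)
  y <- sample(1:5, 70, replace = TRUE)
  mw <- mwu_test(x, y)
  expect_equal(mw$method, "normal approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
})

test_that("KS statistic equals the direct sup-difference computation", {
  set.seed(163)
  for (i in 1:10) {
    x <- rnorm(5 + i, mean = i, sd = 1 + i / 5)
    gate <- normality_gate(list(x))
    expect_equal(gate$statistic, oracle_ks_d(x), tolerance = 1e-12)
  }
})

test_that("normality gate separates normal from skewed samples", {
  set.seed(167)
  normal_ok <- 0; exp_flagged <- 0
  for (i in 1:60) {
    if (normality_gate(list(rnorm(200)))$normal) normal_ok <- normal_ok + 1
    if (!normality_gate(list(rexp(200)))$normal) exp_flagged <- exp_flagged + 1
  }
  expect_gte(normal_ok, 54)   # >= 90%
  expect_gte(exp_flagged, 54)
  expect_warning(gate <- normality_gate(list(rep(2, 10))), "constant")
  expect_false(gate$normal)
})

test_that("two-group comparison gates on normality and stars match p", {
  # identical constant groups take the MWU path and give p = 1
  suppressWarnings(row <- compare_two_groups(rep(1, 5), rep(1, 5)))
  expect_equal(row$test, "MWU")
  expect_equal(row$p, 1)
  # complete separation 3 vs 3 through the gate (constant -> non-normal)
  suppressWarnings(row2 <- compare_two_groups(c(5, 5, 5), c(1, 2, 3)))
  expect_equal(row2$test, "MWU")
  expect_equal(row2$p, 0.1, tolerance = 1e-12)
  # two large normal samples go down the t path
  set.seed(173)
  row3 <- compare_two_groups(rnorm(100), rnorm(100))
  expect_equal(row3$test, "t")
  # star thresholds exactly match p over random draws
  p <- runif(200)
  s <- significance_stars(p)
  expect_identical(s, ifelse(p < 0.001, "***",
                             ifelse(p < 0.01, "**",
                                    ifelse(p < 0.05, "*", ""))))
})

test_that("three-group omnibus tests behave at the boundaries", {
  set.seed(179)
  x <- rnorm(30)
  suppressWarnings(row <- compare_three_groups(x, x, x))
  expect_gt(row$p, 0.99)
  # one clearly shifted group is detected
  row2 <- compare_three_groups(rnorm(30), rnorm(30), rnorm(30, mean = 3))
  expect_lt(row2$p, 0.001)
  # chi-square on identical proportions: statistic 0, p = 1
  tab <- matrix(c(10, 20, 10, 20, 10, 20), 2)
  cs <- chisq_compare(tab)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)
})

test_that("subset correlations are symmetric with exact compositional limits", {
  set.seed(181)
  coh <- small_cohort(n_per_group = 10, n_cells = 150, seed = 191)
  ab <- compute_abundances(oracle_assign(coh), coh$taxonomy,
                           coh$meta$subject_id)
  cm <- subset_correlations(ab, coh$meta$group, taxonomy = coh$taxonomy)
  for (g in names(cm)) {
    expect_equal(cm[[g]]$rho, t(cm[[g]]$rho), tolerance = 1e-12)
    expect_equal(unname(diag(cm[[g]]$rho)), rep(1, nrow(cm[[g]]$rho)))
    expect_true(all(abs(cm[[g]]$rho) <= 1 + 1e-12))
  }
  # two-type composition: fractions are complements, rho exactly -1
  f <- runif(12, 0.2, 0.8)
  ab2 <- cbind(A = f, B = 1 - f)
  cm2 <- subset_correlations(ab2, rep("g", 12), subsets = c("A", "B"))
  expect_equal(cm2$g$rho["A", "B"], -1)
  # planted correlated pair is recovered
  z <- rnorm(25)
  ab3 <- cbind(u = pnorm(0.9 * z + sqrt(1 - 0.81) * rnorm(25)),
               v = pnorm(z))
  cm3 <- subset_correlations(ab3, rep("g", 25), subsets = c("u", "v"))
  expect_gt(cm3$g$rho["u", "v"], 0.6)
  # constant subset flagged with rho 0
  ab4 <- cbind(c1 = rep(0.5, 10), x = runif(10))
  cm4 <- subset_correlations(ab4, rep("g", 10), subsets = c("c1", "x"))
  expect_true(cm4$g$constant["c1"])
  expect_equal(cm4$g$rho["c1", "x"], 0)
})
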