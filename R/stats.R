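#' Normality gate via the Kolmogorov-Smirnov test
#'
#' One-sample KS test of each group against a normal distribution with the
#' group's own sample mean and sd (the SPSS-style usage; estimating the
#' parameters from the sample makes the test anti-conservative — a
#' Lilliefors-corrected or Shapiro-Wilk gate is available via `method`).
#' A group is called normal when the KS p-value exceeds `alpha`. Constant
#' groups are non-normal by convention (with a warning).
#'
#' @param x_by_group List of numeric vectors, one per group (>= 3 values
#'   each).
#' @param alpha Normality cutoff on the test p-value.
#' @param method `"ks"` (default) or `"shapiro"`.
#' @return Data frame per group: `n`, `statistic`, `p`, `normal`.
#' @export
normality_gate <- function(x_by_group, alpha = 0.05,
                           method = c("ks", "shapiro")) {
  method <- match.arg(method)
  if (!is.list(x_by_group)) x_by_group <- list(x_by_group)
  out <- lapply(x_by_group, function(x) {
    if (length(x) < 3) stop("need >= 3 values per group")
    if (var(x) == 0) {
      warning("constant group treated as non-normal")
      return(data.frame(n = length(x), statistic = NA_real_, p = 0,
                        normal = FALSE))
    }
    tst <- if (method == "ks")
      suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    else stats::shapiro.test(x)
    data.frame(n = length(x), statistic = unname(tst$statistic),
               p = tst$p.value, normal = tst$p.value > alpha)
  })
  res <- do.call(rbind, out)
  rownames(res) <- names(x_by_group) %||% seq_along(x_by_group)
  res
}

#' Normality-gated two-group comparison
#'
#' Runs the independent-sample two-sided t-test when both groups pass the
#' KS normality gate, and the Mann-Whitney U test otherwise; stars mark
#' p < 0.05 (*), < 0.01 (**), < 0.001 (***).
#'
#' @param x,y Numeric samples (>= 3 each).
#' @param var_equal Pooled-variance t-test (classic independent-samples
#'   form) when `TRUE`.
#' @return One-row data frame: group summaries, `test`, `statistic`, `p`,
#'   `stars`, and the per-group normality p-values.
#' @export
compare_two_groups <- function(x, y, var_equal = TRUE) {
  gate <- normality_gate(list(x = x, y = y))
  if (all(gate$normal)) {
    tt <- t.test(x, y, var.equal = var_equal)
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    mw <- mwu_test(x, y)
    test <- "MWU"; statistic <- mw$u; p <- mw$p
  }
  data.frame(mean_x = mean(x), mean_y = mean(y),
             median_x = median(x), median_y = median(y),
             test = test, statistic = statistic, p = p,
             stars = significance_stars(p),
             normal_p_x = gate$p[1], normal_p_y = gate$p[2])
}

#' Normality-gated three-group omnibus comparison
#'
#' One-way ANOVA when all groups pass the KS normality gate, Kruskal-Wallis
#' otherwise. Categorical columns use [chisq_compare()].
#'
#' @param x,y,z Numeric samples (>= 3 each).
#' @return One-row data frame: `test`, `statistic`, `p`, `stars`, per-group
#'   normality p-values.
#' @export
compare_three_groups <- function(x, y, z) {
  gate <- normality_gate(list(x = x, y = y, z = z))
  vals <- c(x, y, z)
  grp <- factor(rep(c("x", "y", "z"), c(length(x), length(y), length(z))))
  if (all(gate$normal)) {
    fit <- aov(vals ~ grp)
    sm <- summary(fit)[[1]]
    test <- "ANOVA"; statistic <- sm$`F value`[1]; p <- sm$`Pr(>F)`[1]
  } else {
    kw <- kruskal.test(vals, grp)
    test <- "Kruskal-Wallis"; statistic <- unname(kw$statistic)
    p <- kw$p.value
  }
  data.frame(test = test, statistic = statistic, p = p,
             stars = significance_stars(p),
             normal_p_x = gate$p[1], normal_p_y = gate$p[2],
             normal_p_z = gate$p[3])
}

#' Chi-square test for a categorical contingency table
#'
#' @param tab Contingency table (matrix or `table`).
#' @param correct Yates continuity correction (off by default).
#' @return One-row data frame: `test`, `statistic`, `df`, `p`, `stars`.
#' @export
chisq_compare <- function(tab, correct = FALSE) {
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  data.frame(test = "chi-square", statistic = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value,
             stars = significance_stars(ct$p.value))
}

#' Spearman correlation matrices between subset abundances, per group
#'
#' For each subject group, pairwise Spearman correlations between the
#' chosen abundance subsets, with two-sided p-values (t approximation) and
#' a significance mask at `alpha`. Constant subsets get rho 0 and are
#' flagged.
#'
#' @param abundance Subjects x groups abundance matrix (from
#'   [compute_abundances()]).
#' @param groups Group label per subject.
#' @param subsets Columns to correlate; default takes tier-2 + tier-3
#'   subsets whose cohort prevalence (mean fraction) is at least
#'   `min_prevalence`, via `taxonomy`.
#' @param taxonomy Taxonomy used for the default subset panel.
#' @param min_prevalence Prevalence cutoff for the default panel.
#' @param alpha Significance mask threshold.
#' @return Named list per group of class `correlation_matrix`: `rho`, `p`,
#'   `significant`, `constant`.
#' @export
subset_correlations <- function(abundance, groups, subsets = NULL,
                                taxonomy = NULL, min_prevalence = 0.005,
                                alpha = 0.05) {
  if (is.null(subsets)) {
    if (is.null(taxonomy)) stop("give either subsets or a taxonomy")
    cand <- c(taxonomy$tier2$name, taxonomy$tier3$name)
    cand <- intersect(cand, colnames(abundance))
    subsets <- cand[colMeans(abundance[, cand, drop = FALSE]) >=
                      min_prevalence]
  }
  out <- list()
  for (g in unique(groups)) {
    sub <- abundance[groups == g, subsets, drop = FALSE]
    if (nrow(sub) < 5) stop("group ", g, " has fewer than 5 subjects")
    m <- length(subsets)
    rho <- matrix(1, m, m, dimnames = list(subsets, subsets))
    pm <- matrix(0, m, m, dimnames = list(subsets, subsets))
    constant <- apply(sub, 2, var) == 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (j <= i) next
      if (constant[i] || constant[j]) {
        rho[i, j] <- rho[j, i] <- 0
        pm[i, j] <- pm[j, i] <- 1
      } else {
        sp <- spearman_rank_p(sub[, i], sub[, j])
        rho[i, j] <- rho[j, i] <- sp["rho"]
        pm[i, j] <- pm[j, i] <- sp["p"]
      }
    }
    diag(rho) <- 1; diag(pm) <- 0
    out[[g]] <- structure(list(rho = rho, p = pm,
                               significant = pm < alpha,
                               constant = constant),
                          class = "correlation_matrix")
  }
  out
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix:", nrow(x$rho), "subsets;",
      sum(x$significant[upper.tri(x$significant)]),
      "significant pair(s)\n")
  invisible(x)
}
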