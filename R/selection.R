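#' Rank features by Spearman association with a two-group contrast
#'
#' Computes, for every feature, the Spearman rank correlation between the
#' feature and the binary group label (encoded 1 for the first-named group
#' of the pair and 0 for the second), with the two-sided p-value from the
#' t approximation on n - 2 degrees of freedom. Features are sorted by
#' ascending p; ties in p break by descending |rho|, then feature name.
#' Zero-variance features are dropped with a warning before ranking.
#'
#' @param fm An `immune_feature_matrix` or numeric subjects x features
#'   matrix.
#' @param labels Binary group labels per subject: a 0/1 vector, logical, or
#'   a factor/character with exactly two levels (first level encoded 1).
#' @return A `feature_ranking` data frame (class keeps the sorted order):
#'   columns `feature`, `rho`, `p`, `neg_log10_p`, with attributes `n` and
#'   `label_encoding`.
#' @export
rank_features <- function(fm, labels) {
  values <- if (inherits(fm, "immune_feature_matrix")) fm$values else
    as.matrix(fm)
  enc <- encode_binary_labels(labels)
  y <- enc$y
  if (length(y) != nrow(values))
    stop("labels and feature matrix disagree on subjects")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < 4) stop("need at least 4 subjects per class")
  keep <- apply(values, 2, function(v) var(v) > 0)
  if (any(!keep))
    warning(sum(!keep), " zero-variance feature(s) dropped before ranking")
  values <- values[, keep, drop = FALSE]
  ry <- rank(y)
  stats <- apply(values, 2, function(v) spearman_rank_p(v, ry))
  out <- data.frame(feature = colnames(values), rho = stats["rho", ],
                    p = stats["p", ], row.names = NULL)
  out$p <- pmax(out$p, .Machine$double.xmin)    # guard -log10 against 0
  out <- out[order(out$p, -abs(out$rho), out$feature), ]
  out$neg_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  attr(out, "n") <- length(y)
  attr(out, "label_encoding") <- enc$encoding
  class(out) <- c("feature_ranking", "data.frame")
  out
}

# normalise labels to 0/1 with 1 = first-named level
encode_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lev <- if (is.factor(labels)) levels(droplevels(as.factor(labels)))
    else unique(labels)
    if (length(lev) != 2) stop("labels must have exactly two levels")
    list(y = as.integer(labels == lev[1]),
         encoding = setNames(c(1, 0), lev))
  } else {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    list(y = y, encoding = c(`1` = 1, `0` = 0))
  }
}

#' Select the leading feature block at the cumulative -log10(p) inflection
#'
#' With features sorted by ascending p, the cumulative sum of -log10(p)
#' rises steeply over the informative block and flattens over the noise
#' plateau; the curvature of that curve is concentrated at the boundary
#' between the two regimes. The discrete first difference of the curve is
#' -log10(p_k) itself; on sorted p it is non-increasing, so the discrete
#' second difference is non-positive throughout and the inflection is the
#' rank where the curvature break occurs. It is located by the two-segment
#' breakpoint of the curve: the smallest rank `k` minimising the
#' least-squares error of fitting the first-difference sequence with one
#' level before `k+1` and another after (equivalently, fitting the
#' cumulative curve with two line segments meeting at `k`); ranks `1..k`
#' are selected. When the curve carries no curvature structure (all second
#' differences equal within `tol`, as for identical or geometric
#' p-sequences) or fewer than 3 features are ranked, the fallback selects
#' every feature with p < `fallback_alpha`.
#'
#' @param ranking A `feature_ranking` from [rank_features()].
#' @param tol Degeneracy tolerance on the spread of second differences.
#' @param fallback_alpha Raw-p cutoff used by the fallback (no
#'   multiple-testing correction: selection follows sorted raw p-values).
#' @return The ranking with columns `cum_neg_log10_p`, `first_diff`,
#'   `second_diff`, `selected` added, plus attributes `inflection_index`
#'   and `fallback` (logical).
#' @export
select_inflection <- function(ranking, tol = 1e-12, fallback_alpha = 0.05) {
  stopifnot(inherits(ranking, "feature_ranking"))
  K <- nrow(ranking)
  fd <- ranking$neg_log10_p
  cum <- cumsum(fd)
  sdiff <- if (K >= 2) c(diff(fd), NA_real_) else rep(NA_real_, K)
  ranking$cum_neg_log10_p <- cum
  ranking$first_diff <- fd
  ranking$second_diff <- sdiff
  sd_use <- sdiff[seq_len(max(K - 1, 0))]
  fallback <- K < 3 || diff(range(sd_use)) < tol
  if (fallback) {
    sel <- ranking$p < fallback_alpha
    k <- if (any(sel)) max(which(sel)) else 0L
  } else {
    k <- inflection_breakpoint(fd)
    sel <- seq_len(K) <= k
  }
  ranking$selected <- sel
  attr(ranking, "inflection_index") <- as.integer(k)
  attr(ranking, "fallback") <- fallback
  ranking
}

# smallest k in 1..K-1 minimising the two-segment least-squares error of
# the first-difference sequence split after rank k (prefix-sum form)
inflection_breakpoint <- function(fd) {
  K <- length(fd)
  s1 <- cumsum(fd); s2 <- cumsum(fd^2)
  sse <- vapply(seq_len(K - 1), function(k) {
    n2 <- K - k
    (s2[k] - s1[k]^2 / k) +
      ((s2[K] - s2[k]) - (s1[K] - s1[k])^2 / n2)
  }, numeric(1))
  which.min(sse)          # which.min takes the smallest index on ties
}

#' Re-rank features within sex-defined subgroups
#'
#' Repeats the Spearman ranking after regrouping subjects by sex (e.g.
#' male cases + male controls vs female cases + female controls, or male
#' cases vs all controls), and tabulates -log10(p) across subgroups for a
#' named feature list. Subgroups with fewer than 4 subjects in either class
#' are skipped with a warning.
#'
#' @param fm An `immune_feature_matrix` (or matrix) over all subjects.
#' @param meta Subject metadata with `subject_id`, `group`, `sex`.
#' @param partitions Named list; each element is a list with `subjects`
#'   (ids to keep) and optionally `pair` (two group labels; defaults to the
#'   two groups present). See [sex_partitions()] for the standard splits.
#' @param features Optional feature names for the comparison table
#'   (defaults to the union of each subgroup's top 10).
#' @return List with `rankings` (named list of `feature_ranking`) and
#'   `table` (features x subgroups matrix of -log10 p).
#' @export
subgroup_rescan <- function(fm, meta, partitions, features = NULL) {
  values <- if (inherits(fm, "immune_feature_matrix")) fm$values else
    as.matrix(fm)
  stopifnot(all(c("subject_id", "group") %in% names(meta)))
  rankings <- list()
  for (nm in names(partitions)) {
    part <- partitions[[nm]]
    keep <- meta$subject_id %in% part$subjects
    sub_meta <- meta[keep, , drop = FALSE]
    pair <- part$pair %||% unique(sub_meta$group)
    if (length(pair) != 2) {
      warning("subgroup '", nm, "' does not define two classes; skipped")
      next
    }
    idx <- match(sub_meta$subject_id, rownames(values))
    labs <- factor(sub_meta$group, levels = pair)
    if (min(table(labs)) < 4) {
      warning("subgroup '", nm, "' has < 4 subjects in a class; skipped")
      next
    }
    rankings[[nm]] <- suppressWarnings(
      rank_features(values[idx, , drop = FALSE], labs))
  }
  if (length(rankings) == 0) stop("no subgroup could be ranked")
  if (is.null(features))
    features <- unique(unlist(lapply(rankings, function(r)
      r$feature[seq_len(min(10, nrow(r)))])))
  tab <- sapply(rankings, function(r)
    r$neg_log10_p[match(features, r$feature)])
  tab <- matrix(tab, nrow = length(features),
                dimnames = list(features, names(rankings)))
  list(rankings = rankings, table = tab)
}

#' Standard sex-based partitions of a two-group model
#'
#' Builds the two regroupings used for sex-effect scans: per-sex
#' case/control strata, and each sex's cases against all controls.
#'
#' @param meta Subject metadata (`subject_id`, `group`, `sex`).
#' @param pair Two group labels, case first.
#' @return Named list of partitions suitable for [subgroup_rescan()].
#' @export
sex_partitions <- function(meta, pair) {
  stopifnot(length(pair) == 2)
  case <- pair[1]; ctrl <- pair[2]
  keep <- meta$group %in% pair
  m <- meta[keep, ]
  list(
    male_case_male_ctrl = list(
      subjects = m$subject_id[m$sex == "M"], pair = pair),
    female_case_female_ctrl = list(
      subjects = m$subject_id[m$sex == "F"], pair = pair),
    male_case_all_ctrl = list(
      subjects = m$subject_id[(m$group == case & m$sex == "M") |
                                m$group == ctrl], pair = pair),
    female_case_all_ctrl = list(
      subjects = m$subject_id[(m$group == case & m$sex == "F") |
                                m$group == ctrl], pair = pair))
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("feature_ranking:", nrow(x), "features")
  if (!is.null(attr(x, "inflection_index")))
    cat("; ", sum(x$selected), " selected (inflection at rank ",
        attr(x, "inflection_index"),
        if (isTRUE(attr(x, "fallback"))) ", fallback path" else "", ")",
        sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}
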