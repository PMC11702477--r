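#' Mann-Whitney U test (rank-sum), two-sided
#'
#' The U statistic is computed from midranks, so `U / (n1 * n2)` is exactly
#' the rank AUC of `x` against `y`. The two-sided p-value is exact where
#' tractable: full enumeration of all rank splits when both groups have at
#' most 8 values (valid under ties); the exact tie-free null distribution
#' when there are no ties and both groups have at most 50 values; otherwise
#' the normal approximation with tie correction. Exact two-sided p is
#' defined symmetrically: the null probability that `|U - n1 n2 / 2|` is at
#' least as large as observed.
#'
#' @param x,y Numeric samples for the two groups.
#' @return List with `u` (U of `x` over `y`), `p`, `auc` (= `u/(n1*n2)`),
#'   and `method`.
#' @export
mwu_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  mid <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    method <- "exact enumeration"
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mid) >= abs(u - mid) - 1e-9)
  } else if (!ties && n1 <= 50 && n2 <= 50) {
    method <- "exact distribution"
    us <- 0:(n1 * n2)
    dens <- stats::dwilcox(us, n1, n2)
    p <- sum(dens[abs(us - mid) >= abs(u - mid) - 1e-9])
  } else {
    method <- "normal approximation"
    n <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1, auc = u / (n1 * n2),
                                 method = method))
    z <- (u - mid) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(u = u, p = min(p, 1), auc = u / (n1 * n2), method = method)
}

#' ROC curve points for a score against binary labels
#'
#' @param score Numeric scores (higher = more case-like).
#' @param y Binary labels (1 = case).
#' @return Data frame of `threshold`, `fpr`, `tpr`, sorted for plotting.
#' @export
roc_points <- function(score, y) {
  y <- as.integer(y)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(score[y == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[y == 0] >= t), 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Univariate (or paired) biomarker ROC
#'
#' AUC of a single scalar biomarker by rank statistic (midranks under
#' ties). A pair of biomarkers is combined into one score by fitting an
#' unpenalised two-feature logistic model on all modelled subjects and
#' scoring its linear predictor.
#'
#' @param meta Subject metadata containing the biomarker column(s).
#' @param markers One or two biomarker column names.
#' @param labels Binary labels aligned with `meta` rows (two-level
#'   factor/character, first level = case, or 0/1).
#' @return List with `auc`, `roc` (curve points), and `score`.
#' @export
univariate_roc <- function(meta, markers, labels) {
  stopifnot(all(markers %in% names(meta)), length(markers) %in% 1:2)
  y <- encode_binary_labels(labels)$y
  vals <- as.matrix(meta[, markers, drop = FALSE])
  if (anyNA(vals)) stop("missing biomarker values among modelled subjects")
  if (length(markers) == 1) {
    score <- vals[, 1]
    if (var(score) == 0) {
      warning("constant biomarker '", markers, "'; AUC set to 0.5")
      return(list(auc = 0.5, roc = roc_points(score, y), score = score))
    }
  } else {
    df <- data.frame(y = y, vals)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    score <- drop(predict(fit, type = "link"))
  }
  list(auc = rank_auc(score, y), roc = roc_points(score, y), score = score)
}
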