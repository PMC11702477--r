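#' Immunological elastic net with repeated cross-validation
#'
#' Fits a prior-weighted elastic-net logistic classifier and evaluates it by
#' repeated stratified k-fold cross-validation: per repetition, a fresh
#' stratified fold split; per training fold-set, the penalty strength
#' `lambda` is chosen by inner cross-validated binomial deviance over a log
#' grid, the model is refit at that `lambda`, and the held-out subjects'
#' linear predictors are collected. Out-of-fold predictions are averaged
#' over repetitions; the aggregated predictions yield the model AUC (rank
#' statistic, midranks for ties) and a two-sided Mann-Whitney p-value
#' between the two classes.
#'
#' Per-feature penalty factors derive from prior scores via
#' [prior_weights()]; with `phi = 0` or uniform priors this is the standard
#' elastic net. A final model is also fit on all subjects at the median of
#' the cross-validation-selected lambdas, and backs [predict.ien()] and
#' [coef.ien()].
#'
#' @param x Subjects x features matrix or `immune_feature_matrix`.
#' @param y Binary labels (two-level factor/character, first level = case,
#'   or 0/1).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param prior Per-feature prior scores in `[0, 1]` (default 0: uniform).
#' @param phi Prior influence exponent (default 0: priors inert).
#' @param n_repeats Cross-validation repetitions (study scheme: 100).
#' @param n_folds Outer folds (study scheme: 10).
#' @param inner_folds Folds for the inner lambda search.
#' @param n_lambda,lambda_min_ratio Lambda grid: `n_lambda` log-spaced
#'   points from the training-set `lambda_max` down `lambda_min_ratio`
#'   (default 50 points over 3 decades).
#' @param seed Mandatory RNG seed; each repetition draws from a stream
#'   derived from `(seed, repetition)`, so results are reproducible and
#'   repetition r is invariant to `n_repeats`.
#' @return An object of class `ien`: aggregated per-subject predictions
#'   (`predictions`), per-repetition AUC (`auc_per_repeat`), aggregate
#'   `auc`, Mann-Whitney `mwu_p`, nonzero-coefficient selection frequency
#'   (`coef_frequency`), the final full-data `enet_fit` (`final_fit`,
#'   `final_lambda`), hyperparameters and label encoding.
#' @seealso [enet_logistic()], [prior_weights()], [univariate_roc()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 10), 40)
#' y <- rep(c("case", "control"), each = 20)
#' x[, 1] <- x[, 1] + ifelse(y == "case", 2, 0)
#' fit <- ien(x, y, n_repeats = 3, seed = 7)
#' fit$auc
#' @export
ien <- function(x, y, alpha = 0.5, prior = NULL, phi = 0,
                n_repeats = 100, n_folds = 10, inner_folds = 5,
                n_lambda = 50, lambda_min_ratio = 1e-3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  values <- if (inherits(x, "immune_feature_matrix")) x$values else
    as.matrix(x)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  enc <- encode_binary_labels(y)
  yb <- enc$y
  n <- nrow(values); p <- ncol(values)
  if (length(yb) != n) stop("x and y disagree on subjects")
  if (min(table(yb)) < 2) stop("need at least 2 subjects per class")
  prior <- if (is.null(prior)) rep(0, p) else rep_len(prior, p)
  pf <- prior_weights(prior, phi)

  eta_mat <- matrix(NA_real_, n, n_repeats)
  auc_rep <- numeric(n_repeats)
  nz_count <- setNames(numeric(p), colnames(values))
  n_fits <- 0L
  lambdas_chosen <- c()
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, r))
    fold <- make_valid_folds(yb, n_folds)
    eta <- rep(NA_real_, n)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      cvfit <- cv_lambda_fit(values[tr, , drop = FALSE], yb[tr], alpha, pf,
                             inner_folds, n_lambda, lambda_min_ratio)
      eta[!tr] <- drop(values[!tr, , drop = FALSE] %*% cvfit$beta +
                         cvfit$intercept)
      nz_count <- nz_count + (cvfit$beta != 0)
      n_fits <- n_fits + 1L
      lambdas_chosen <- c(lambdas_chosen, cvfit$lambda)
    }
    eta_mat[, r] <- eta
    auc_rep[r] <- rank_auc(eta, yb)
  }
  agg <- rowMeans(eta_mat)
  auc <- rank_auc(agg, yb)
  mwu <- mwu_test(agg[yb == 1], agg[yb == 0])

  final_lambda <- median(lambdas_chosen)
  final <- enet_logistic(values, yb, alpha = alpha, lambda = final_lambda,
                         penalty_factor = pf, max_sweeps = 1e5)
  structure(list(predictions = setNames(agg, rownames(values)),
                 eta_matrix = eta_mat, y = yb,
                 auc_per_repeat = auc_rep, auc = auc,
                 mwu_p = mwu$p, mwu_u = mwu$u,
                 coef_frequency = nz_count / n_fits,
                 final_fit = final, final_lambda = final_lambda,
                 hyperparameters = list(alpha = alpha, phi = phi,
                                        n_repeats = n_repeats,
                                        n_folds = n_folds,
                                        inner_folds = inner_folds,
                                        n_lambda = n_lambda,
                                        lambda_min_ratio = lambda_min_ratio),
                 label_encoding = enc$encoding, seed = seed,
                 feature_names = colnames(values)),
            class = "ien")
}

# stratified folds; refold (fresh draw) if any training set lacks a class,
# up to 10 attempts
make_valid_folds <- function(y, n_folds) {
  for (attempt in 1:10) {
    fold <- stratified_folds(y, n_folds)
    ok <- all(vapply(unique(fold), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training set")
}

# choose lambda on a training set by inner-CV deviance, refit at the winner
cv_lambda_fit <- function(xtr, ytr, alpha, pf, inner_folds, n_lambda,
                          lambda_min_ratio) {
  center <- colMeans(xtr)
  scale_ <- sqrt(colMeans(sweep(xtr, 2, center)^2))
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(xtr, 2, center), 2, scale_, "/")
  lmax <- lambda_max(xs, ytr, alpha, pf)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  k <- min(inner_folds, min(table(ytr)))
  dev <- matrix(NA_real_, k, n_lambda)
  fold <- stratified_folds(ytr, k)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(ytr[tr])) < 2) next
    fit <- enet_logistic(xtr[tr, , drop = FALSE], ytr[tr], alpha = alpha,
                         lambda = grid, penalty_factor = pf)
    etas <- as.matrix(xtr[!tr, , drop = FALSE]) %*% fit$beta +
      matrix(fit$intercept, sum(!tr), n_lambda, byrow = TRUE)
    dev[f, ] <- apply(etas, 2, binomial_deviance, y = ytr[!tr])
  }
  mdev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(mdev)
  fit <- enet_logistic(xtr, ytr, alpha = alpha, lambda = grid,
                       penalty_factor = pf)
  list(beta = fit$beta[, best], intercept = fit$intercept[best],
       lambda = grid[best])
}

#' @export
print.ien <- function(x, ...) {
  h <- x$hyperparameters
  cat("Immunological elastic net (", h$n_repeats, "x ", h$n_folds,
      "-fold CV, alpha = ", h$alpha, ", phi = ", h$phi, ")\n", sep = "")
  cat(sprintf("  aggregate AUC: %.3f   Mann-Whitney p: %.3g\n",
              x$auc, x$mwu_p))
  cat("  nonzero features (final fit):", sum(x$final_fit$beta != 0), "of",
      length(x$feature_names), "\n")
  invisible(x)
}

#' Summarise an `ien` model
#'
#' @param object An `ien` fit.
#' @param n_top Number of top features (by selection frequency) to show.
#' @param ... Unused.
#' @return An object of class `summary.ien`, printed with the aggregate
#'   AUC, per-repetition AUC spread, Mann-Whitney p and the most frequently
#'   selected features.
#' @export
summary.ien <- function(object, n_top = 10, ...) {
  top <- sort(object$coef_frequency, decreasing = TRUE)
  top <- top[top > 0]
  out <- list(auc = object$auc,
              auc_range = range(object$auc_per_repeat),
              auc_sd = sd(object$auc_per_repeat),
              mwu_p = object$mwu_p,
              top_features = utils::head(top, n_top),
              hyperparameters = object$hyperparameters)
  class(out) <- "summary.ien"
  out
}

#' @export
print.summary.ien <- function(x, ...) {
  cat(sprintf("aggregate AUC %.3f (per-repetition %.3f-%.3f, sd %.3f)\n",
              x$auc, x$auc_range[1], x$auc_range[2], x$auc_sd))
  cat(sprintf("Mann-Whitney two-sided p: %.3g\n", x$mwu_p))
  cat("most frequently selected features:\n")
  print(round(x$top_features, 3))
  invisible(x)
}

#' Coefficients of the final full-data fit
#'
#' @param object An `ien` fit.
#' @param ... Unused.
#' @return Named coefficient vector (intercept first); attribute
#'   `frequency` carries each feature's nonzero selection frequency across
#'   cross-validation fits.
#' @export
coef.ien <- function(object, ...) {
  out <- c(`(Intercept)` = object$final_fit$intercept[1],
           drop(object$final_fit$beta[, 1]))
  attr(out, "frequency") <- object$coef_frequency
  out
}

#' Predict from an `ien` model
#'
#' Scores new subjects with the final full-data fit.
#'
#' @param object An `ien` fit.
#' @param newx New subjects x features matrix (same features); omitting it
#'   returns the aggregated out-of-fold predictions ("link" only).
#' @param type `"link"`, `"response"`, or `"class"`.
#' @param ... Unused.
#' @return Numeric vector (or labels for `"class"`).
#' @export
predict.ien <- function(object, newx = NULL,
                        type = c("link", "response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newx)) {
    if (type != "link")
      stop("without newx only the aggregated out-of-fold link is available")
    return(object$predictions)
  }
  eta <- predict(object$final_fit, newx, s = 1, type = "link")
  switch(type,
         link = eta,
         response = 1 / (1 + exp(-eta)),
         class = {
           lab <- names(object$label_encoding)
           ifelse(eta > 0, lab[1], lab[2])
         })
}

#' ROC curve of the aggregated cross-validated predictions
#'
#' @param x An `ien` fit.
#' @param ... Passed to [plot()].
#' @return The ROC points, invisibly.
#' @export
plot.ien <- function(x, ...) {
  roc <- roc_points(x$predictions, x$y)
  plot(roc$fpr, roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("iEN aggregated CV predictions (AUC = %.3f)", x$auc),
       ...)
  abline(0, 1, lty = 3)
  invisible(roc)
}

#' Residuals of the aggregated cross-validated predictions
#'
#' @param object An `ien` fit.
#' @param ... Unused.
#' @return Response residuals `y - p_hat` on the aggregated out-of-fold
#'   probabilities.
#' @export
residuals.ien <- function(object, ...) {
  object$y - 1 / (1 + exp(-object$predictions))
}
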