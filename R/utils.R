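# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# cosine similarity of two vectors; 0 if either has zero norm
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# derive a child RNG seed from (seed, index); kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# significance stars at the conventional thresholds
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

# Spearman rho with average ranks plus two-sided p from the t approximation
# on n - 2 degrees of freedom (the convention used throughout the package)
spearman_rank_p <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(cor(rank(x), rank(y)))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

# rank-based AUC of score x for binary label y (1 = positive), midranks for ties
rank_auc <- function(x, y) {
  stopifnot(length(x) == length(y))
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("rank_auc() needs both classes present")
  r <- rank(x)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment; classes shuffled independently so each fold
# carries both classes wherever sizes allow
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(n_folds), length(idx))
  }
  fold
}
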