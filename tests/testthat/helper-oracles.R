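# Independent oracles used to cross-check package computations. Each is a
# naive, direct implementation that shares no code with the functions under
# test.

# ridge-penalized logistic regression by plain IRLS with an explicit
# (p x p) solve; objective -(1/n) loglik + lambda/2 * sum(beta^2),
# intercept unpenalized
oracle_ridge_logistic <- function(X, y, lambda, maxit = 200, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  beta <- rep(0, p + 1)
  pen <- diag(c(0, rep(lambda, p)))
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    W <- mu * (1 - mu)
    grad <- drop(crossprod(Z, y - mu)) / n - pen %*% beta
    hess <- crossprod(Z * W, Z) / n + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# two-sided Mann-Whitney p by complete enumeration of all C(n1+n2, n1)
# assignments of the pooled (mid)ranks; symmetric distance from n1*n2/2
oracle_mwu_enumeration <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# Kolmogorov-Smirnov D against N(mean(x), sd(x)) by direct sup over the
# empirical-cdf jump points
oracle_ks_d <- function(x) {
  n <- length(x)
  xs <- sort(x)
  F0 <- pnorm(xs, mean(x), sd(x))
  max(pmax(abs(seq_len(n) / n - F0), abs((seq_len(n) - 1) / n - F0)))
}

# brute-force two-segment breakpoint scan of the sorted -log10(p) sequence:
# for every candidate cut, fit each side with its mean and accumulate
# squared error by explicit loops
oracle_inflection <- function(p_sorted) {
  fd <- -log10(p_sorted)
  K <- length(fd)
  best_k <- NA_integer_; best_sse <- Inf
  for (k in seq_len(K - 1)) {
    m1 <- mean(fd[1:k]); m2 <- mean(fd[(k + 1):K])
    sse <- 0
    for (i in 1:k) sse <- sse + (fd[i] - m1)^2
    for (i in (k + 1):K) sse <- sse + (fd[i] - m2)^2
    if (sse < best_sse - 1e-15) { best_sse <- sse; best_k <- k }
  }
  best_k
}

# naive rank AUC by pairwise comparison (ties count half)
oracle_pairwise_auc <- function(x, y) {
  pos <- x; neg <- y
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
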