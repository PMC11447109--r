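# Minimal exact Gaussian-process regression with a Matern-5/2 kernel, used as
# the Bayesian-optimization surrogate. Targets are standardized internally;
# the length-scale is chosen by marginal likelihood over a small grid around
# the median pairwise distance.

matern52 <- function(D, lengthscale) {
  s <- sqrt(5) * D / lengthscale
  (1 + s + s^2 / 3) * exp(-s)
}

cross_dist <- function(X1, X2) {
  # Euclidean distances between rows of X1 and rows of X2
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  sqrt(pmax(d2, 0))
}

gp_fit <- function(X, y, jitter = 1e-6, lengthscale_bounds = c(1e-3, 1e3)) {
  X <- as.matrix(X)
  n <- nrow(X)
  ymu <- mean(y)
  ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd <= 0) ysd <- 1
  ys <- (y - ymu) / ysd
  D <- cross_dist(X, X)
  med <- stats::median(D[upper.tri(D)])
  if (!is.finite(med) || med <= 0) med <- 1
  cand <- pmin(pmax(med * c(0.25, 0.5, 1, 2, 4), lengthscale_bounds[1]),
               lengthscale_bounds[2])
  best <- NULL
  for (l in unique(cand)) {
    fit <- gp_chol(D, ys, l, jitter)
    if (!is.null(fit) && (is.null(best) || fit$logml > best$logml)) best <- fit
  }
  if (is.null(best)) stop_numeric("GP surrogate fit failed: degenerate covariance")
  c(best, list(X = X, ymu = ymu, ysd = ysd, n = n))
}

gp_chol <- function(D, ys, lengthscale, jitter) {
  n <- nrow(D)
  # jitter escalation: three attempts, x100 each, then give up on this scale
  for (attempt in 0:2) {
    jit <- jitter * 100^attempt
    K <- matern52(D, lengthscale) + diag(jit, n)
    L <- tryCatch(t(chol(K)), error = function(e) NULL)
    if (is.null(L)) next
    alpha <- backsolve(t(L), forwardsolve(L, ys))
    logml <- -0.5 * sum(ys * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
    return(list(L = L, alpha = alpha, lengthscale = lengthscale,
                jitter = jit, logml = logml))
  }
  NULL
}

gp_predict <- function(gp, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- matern52(cross_dist(Xnew, gp$X), gp$lengthscale)
  mu <- drop(Ks %*% gp$alpha)
  V <- forwardsolve(gp$L, t(Ks))
  var <- pmax(1 + gp$jitter - colSums(V^2), 0)
  list(mean = mu * gp$ysd + gp$ymu, sd = sqrt(var) * gp$ysd)
}

# Expected improvement for minimization.
expected_improvement <- function(mu, sd, best) {
  ei <- numeric(length(mu))
  ok <- sd > 1e-12
  z <- (best - mu[ok]) / sd[ok]
  ei[ok] <- (best - mu[ok]) * stats::pnorm(z) + sd[ok] * stats::dnorm(z)
  pmax(ei, 0)
}
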