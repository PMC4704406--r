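# Independent oracles used across the suite. They share no code with the
# package internals they check.

# Moments of a truncated normal / log-normal by direct quadrature of the
# conditional density.
oracle_trunc_moments <- function(mu, sigma, a, b, lognormal = FALSE) {
  dens <- if (lognormal) function(x) dlnorm(x, mu, sigma)
          else function(x) dnorm(x, mu, sigma)
  Z <- integrate(dens, a, b, rel.tol = 1e-12)$value
  m1 <- integrate(function(x) x * dens(x) / Z, a, b, rel.tol = 1e-12)$value
  m2 <- integrate(function(x) x^2 * dens(x) / Z, a, b, rel.tol = 1e-12)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# PLS1 predictions via the Krylov-subspace characterisation: the k-factor
# PLS1 coefficient vector is the least-squares minimiser of ||y - Xb|| over
# the Krylov space span{X'y, (X'X)X'y, ..., (X'X)^(k-1) X'y}. X and y must
# already be centred/scaled; returns predictions on that scale.
oracle_pls_krylov <- function(X, y, k, X_new = X) {
  p <- ncol(X)
  K <- matrix(0, p, k)
  v <- crossprod(X, y)
  K[, 1] <- v / max(abs(v))
  if (k > 1) {
    for (j in 2:k) {
      v <- crossprod(X, X %*% K[, j - 1])
      K[, j] <- v / max(abs(v))
    }
  }
  Q <- qr.Q(qr(K))
  Z <- X %*% Q
  beta <- qr.coef(qr(Z), y)
  drop(X_new %*% (Q %*% beta))
}

# Small panel of quick-to-simulate analytes for pipeline-level tests.
quick_specs <- function() {
  analyte_registry(c("glucose", "total_cholesterol", "total_protein", "k"))
}

scaled_instance <- function(n, p, seed, sparse_signal = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[seq_len(min(sparse_signal, p))] <- rnorm(min(sparse_signal, p))
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  X <- scale(X)
  y <- drop(scale(y))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, y = y)
}
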