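# PCA, ICA and NMF fits.  Each fit returns a `bombe_model` whose
# user-facing weight matrix W is genes x k: the object interpreted by
# gene-set network projection.

fit_pca <- function(x, k, seed) {
  center <- colMeans(x)
  xc <- sweep(x, 2, center, "-")
  sv <- svd(xc, nu = 0, nv = k)
  W <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(W) <- list(colnames(x), feature_names(k))
  list(W = W, center = center)
}

fit_ica <- function(x, k, seed) {
  center <- colMeans(x)
  fit <- with_seed(seed, ica::icafast(x, nc = k, center = TRUE))
  # icafast: S = Xc %*% t(W_unmix); X ~ S %*% t(M).  Unit-norm weight
  # columns (ICA scale/sign is unidentifiable); the mixing matrix absorbs
  # the compensating norms so reconstruction is unchanged.
  P <- t(fit$W)
  norms <- sqrt(colSums(P^2))
  W <- sweep(P, 2, norms, "/")
  M <- sweep(fit$M, 2, norms, "*")
  dimnames(W) <- list(colnames(x), feature_names(k))
  list(W = W, center = center, mixing = M)
}

fit_nmf <- function(x, k, seed, maxit = 200, tol = 1e-5) {
  stop_if(min(x) < 0, "NMF requires non-negative input")
  n <- nrow(x); p <- ncol(x)
  eps <- 1e-10
  scale0 <- sqrt(mean(x) / k)
  with_seed(seed, {
    Z <- matrix(stats::runif(n * k), n, k) * scale0
    W <- matrix(stats::runif(p * k), p, k) * scale0
  })
  err_prev <- Inf
  for (it in seq_len(maxit)) {
    # Lee-Seung multiplicative updates for the Frobenius objective
    Z <- Z * (x %*% W) / (Z %*% crossprod(W) + eps)
    W <- W * (crossprod(x, Z)) / (W %*% crossprod(Z) + eps)
    if (it %% 10L == 0L) {
      err <- sum((x - tcrossprod(Z, W))^2)
      if (is.finite(err_prev) && (err_prev - err) < tol * err_prev) break
      err_prev <- err
    }
  }
  dimnames(W) <- list(colnames(x), feature_names(k))
  dimnames(Z) <- list(rownames(x), feature_names(k))
  list(W = W, Z = Z)
}

# Non-negative projection of new samples onto fixed NMF gene factors:
# deterministic multiplicative updates on Z alone.
nmf_transform <- function(W, x, maxit = 100) {
  eps <- 1e-10
  WtW <- crossprod(W)
  Z <- matrix(mean(x) / ncol(W), nrow(x), ncol(W))
  for (it in seq_len(maxit)) {
    Z <- Z * (x %*% W) / (Z %*% WtW + eps)
  }
  dimnames(Z) <- list(rownames(x), colnames(W))
  Z
}

feature_names <- function(k) sprintf("feature_%d", seq_len(k) - 1L)
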