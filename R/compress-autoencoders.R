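# Single-bottleneck denoising and variational autoencoders, trained with
# Adam on minibatches.  Architectures are deliberately minimal: one dense
# encoding to the k-dimensional bottleneck and one dense decoding with a
# sigmoid output matched to [0,1]-scaled expression input and a
# binary-cross-entropy reconstruction objective.  The user-facing weight
# matrix is the decoder weight matrix (latent -> genes), transposed to
# genes x k so that its orientation matches the network-projection product.

sigmoid <- function(x) 1 / (1 + exp(-x))

default_ae_hyperparams <- function() {
  list(learning_rate = 5e-4, batch_size = 50, epochs = 50,
       dae_noise_fraction = 0.1, vae_kl_weight = 1)
}

adam_new <- function(params, lr) {
  list(lr = lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1
  corr1 <- 1 - state$b1^state$t
  corr2 <- 1 - state$b2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- state$b1 * state$m[[nm]] + (1 - state$b1) * grads[[nm]]
    state$v[[nm]] <- state$b2 * state$v[[nm]] + (1 - state$b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - state$lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + state$eps)
  }
  list(state = state, params = params)
}

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

fit_dae <- function(x, k, seed, hp) {
  n <- nrow(x); p <- ncol(x)
  with_seed(seed, {
    params <- list(We = glorot(p, k), be = rep(0, k),
                   Wd = glorot(k, p), bd = rep(0, p))
    opt <- adam_new(params, hp$learning_rate)
    for (epoch in seq_len(hp$epochs)) {
      for (batch in minibatches(n, hp$batch_size)) {
        xb <- x[batch, , drop = FALSE]
        b <- nrow(xb)
        # masking noise: randomly zero a fraction of input entries
        mask <- matrix(stats::rbinom(b * p, 1, 1 - hp$dae_noise_fraction), b, p)
        xn <- xb * mask
        z <- xn %*% params$We + rep(params$be, each = b)
        logits <- z %*% params$Wd + rep(params$bd, each = b)
        xhat <- sigmoid(logits)
        dlogit <- (xhat - xb) / b
        grads <- list(
          We = crossprod(xn, dlogit %*% t(params$Wd)),
          be = colSums(dlogit %*% t(params$Wd)),
          Wd = crossprod(z, dlogit),
          bd = colSums(dlogit)
        )
        upd <- adam_step(opt, params, grads)
        opt <- upd$state
        params <- upd$params
      }
    }
    W <- t(params$Wd)
    dimnames(W) <- list(colnames(x), feature_names(k))
    list(W = W, params = params)
  })
}

fit_vae <- function(x, k, seed, hp) {
  n <- nrow(x); p <- ncol(x)
  beta <- hp$vae_kl_weight
  with_seed(seed, {
    params <- list(Wmu = glorot(p, k), bmu = rep(0, k),
                   Wlv = glorot(p, k) * 0.01, blv = rep(0, k),
                   Wd = glorot(k, p), bd = rep(0, p))
    opt <- adam_new(params, hp$learning_rate)
    for (epoch in seq_len(hp$epochs)) {
      for (batch in minibatches(n, hp$batch_size)) {
        xb <- x[batch, , drop = FALSE]
        b <- nrow(xb)
        mu <- xb %*% params$Wmu + rep(params$bmu, each = b)
        lv <- xb %*% params$Wlv + rep(params$blv, each = b)
        lv <- pmin(pmax(lv, -15), 15)
        noise <- matrix(stats::rnorm(b * k), b, k)
        z <- mu + exp(lv / 2) * noise
        logits <- z %*% params$Wd + rep(params$bd, each = b)
        xhat <- sigmoid(logits)
        dlogit <- (xhat - xb) / b
        dz <- dlogit %*% t(params$Wd)
        dmu <- dz + beta * mu / b
        dlv <- dz * noise * 0.5 * exp(lv / 2) + beta * 0.5 * (exp(lv) - 1) / b
        grads <- list(
          Wmu = crossprod(xb, dmu), bmu = colSums(dmu),
          Wlv = crossprod(xb, dlv), blv = colSums(dlv),
          Wd = crossprod(z, dlogit), bd = colSums(dlogit)
        )
        upd <- adam_step(opt, params, grads)
        opt <- upd$state
        params <- upd$params
      }
    }
    W <- t(params$Wd)
    dimnames(W) <- list(colnames(x), feature_names(k))
    list(W = W, params = params)
  })
}
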