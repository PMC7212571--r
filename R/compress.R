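# Fitting compression models over the (algorithm, k, seed) grid and
# evaluating their reconstructions.

BOMBE_ALGORITHMS <- c("pca", "ica", "nmf", "dae", "vae")

#' Default grid of latent dimensionalities
#'
#' The 28 latent dimensionalities, from k = 2 to k = 200, over which the
#' full compression grid is trained.
#'
#' @return integer vector of length 28.
#' @export
default_k_grid <- function() {
  c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 12L, 14L, 16L, 18L, 20L, 25L,
    30L, 35L, 40L, 45L, 50L, 60L, 70L, 80L, 90L, 100L, 125L, 150L, 200L)
}

#' Fit one compression model
#'
#' Trains a single model of the requested algorithm at latent
#' dimensionality `k`.  All five algorithms are deterministic given the
#' seed.  The autoencoders use a single bottleneck layer; the VAE objective
#' is reconstruction BCE plus a KL divergence penalty weighted by
#' `vae_kl_weight`, and the DAE corrupts its input by randomly zeroing a
#' fraction `dae_noise_fraction` of entries per minibatch.
#'
#' @param train samples x genes training matrix, min-max scaled to \[0,1\].
#' @param algorithm one of `"pca"`, `"ica"`, `"nmf"`, `"dae"`, `"vae"`.
#' @param k latent dimensionality, `2 <= k <= min(dim(train))`.
#' @param seed integer seed.
#' @param ae_hyperparams named list overriding autoencoder defaults
#'   (`learning_rate` 5e-4, `batch_size` 50, `epochs` 50,
#'   `dae_noise_fraction` 0.1, `vae_kl_weight` 1).
#' @param data_tag `"real"` or `"permuted"`, recorded for bookkeeping.
#' @return a `bombe_model` with the genes x k weight matrix in `$W`.
#' @export
fit_model <- function(train, algorithm, k, seed = 0,
                      ae_hyperparams = list(), data_tag = "real") {
  check_expression(train)
  algorithm <- match.arg(algorithm, BOMBE_ALGORITHMS)
  stop_if(!is_count(k) || k < 2 || k > min(dim(train)),
          "k must satisfy 2 <= k <= min(samples, genes)")
  if (algorithm == "nmf") {
    stop_if(min(train) < 0, "NMF requires non-negative input values")
  }
  hp <- utils::modifyList(default_ae_hyperparams(), ae_hyperparams)

  fit <- switch(algorithm,
    pca = fit_pca(train, k, seed),
    ica = fit_ica(train, k, seed),
    nmf = fit_nmf(train, k, seed),
    dae = fit_dae(train, k, seed, hp),
    vae = fit_vae(train, k, seed, hp)
  )
  model <- c(fit, list(algorithm = algorithm, k = as.integer(k),
                       seed = as.integer(seed), data_tag = data_tag,
                       gene_ids = colnames(train), hyperparams = hp))
  class(model) <- c(paste0("bombe_", algorithm), "bombe_model")
  model
}

#' @export
print.bombe_model <- function(x, ...) {
  cat(sprintf("bombe_model: %s, k = %d, seed = %d, %d genes (%s data)\n",
              x$algorithm, x$k, x$seed, length(x$gene_ids), x$data_tag))
  invisible(x)
}

check_gene_match <- function(model, data) {
  stop_if(!identical(colnames(data), model$gene_ids),
          "gene set of the data does not match the training gene set; ",
          "use project_external() for transfer across gene universes")
}

#' Sample activation scores of data under a fitted model
#'
#' Maps a samples x genes matrix (same gene universe as training) to the
#' samples x k activation matrix.  A sample's activation on one latent
#' feature summarizes that feature's activity in the sample.
#'
#' @param object a `bombe_model`.
#' @param newdata samples x genes matrix over the training gene set.
#' @param ... unused.
#' @return samples x k activation matrix.
#' @export
predict.bombe_model <- function(object, newdata, ...) {
  check_expression(newdata)
  check_gene_match(object, newdata)
  act <- switch(object$algorithm,
    pca = sweep(newdata, 2, object$center, "-") %*% object$W,
    ica = sweep(newdata, 2, object$center, "-") %*% object$W,
    nmf = nmf_transform(object$W, newdata),
    dae = newdata %*% object$params$We +
      rep(object$params$be, each = nrow(newdata)),
    vae = newdata %*% object$params$Wmu +
      rep(object$params$bmu, each = nrow(newdata))
  )
  dimnames(act) <- list(rownames(newdata), colnames(object$W))
  act
}

#' Reconstruct expression data through a fitted model's bottleneck
#'
#' @param model a `bombe_model`.
#' @param newdata samples x genes matrix over the training gene set.
#' @return samples x genes reconstruction.  Autoencoder outputs pass
#'   through a sigmoid and lie in (0,1); PCA/ICA reconstructions can exit
#'   \[0,1\] and are clipped only inside [reconstruction_bce()].
#' @export
reconstruct <- function(model, newdata) {
  stopifnot(inherits(model, "bombe_model"))
  act <- predict(model, newdata)
  out <- switch(model$algorithm,
    pca = sweep(tcrossprod(act, model$W), 2, model$center, "+"),
    ica = sweep(tcrossprod(act, model$mixing), 2, model$center, "+"),
    nmf = tcrossprod(act, model$W),
    dae = sigmoid(act %*% model$params$Wd +
                    rep(model$params$bd, each = nrow(act))),
    vae = sigmoid(act %*% model$params$Wd +
                    rep(model$params$bd, each = nrow(act)))
  )
  dimnames(out) <- dimnames(newdata)
  out
}

#' Binary cross entropy reconstruction cost
#'
#' Mean over samples of the per-sample mean over genes of
#' `-[x log(xhat) + (1 - x) log(1 - xhat)]` (natural log).  Reconstructions
#' are clipped to `[eps, 1 - eps]` first, since PCA/ICA reconstructions can
#' exit \[0,1\].
#'
#' @param x input matrix with values in \[0,1\].
#' @param xhat reconstruction of the same shape.
#' @param eps clipping constant.
#' @return scalar BCE.
#' @export
reconstruction_bce <- function(x, xhat, eps = 1e-7) {
  stop_if(!identical(dim(x), dim(xhat)), "x and xhat shapes differ")
  xhat <- pmin(pmax(xhat, eps), 1 - eps)
  mean(rowMeans(-(x * log(xhat) + (1 - x) * log(1 - xhat))))
}

#' Per-sample Pearson correlation between input and reconstruction
#'
#' @param x input samples x genes matrix.
#' @param xhat reconstruction of the same shape.
#' @return numeric vector with one correlation per sample; samples whose
#'   input row (or reconstruction row) has zero variance get `NA` and are
#'   excluded from downstream means.
#' @export
sample_pearson <- function(x, xhat) {
  stop_if(!identical(dim(x), dim(xhat)), "x and xhat shapes differ")
  r <- vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]; yi <- xhat[i, ]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) return(NA_real_)
    stats::cor(xi, yi)
  }, numeric(1))
  names(r) <- rownames(x)
  r
}

model_key <- function(algorithm, k, seed, data_tag) {
  paste(algorithm, k, seed, data_tag, sep = "|")
}

#' Train the full compression grid
#'
#' Fits every (algorithm, k, seed) combination on the real training data
#' and, optionally, on a gene-permuted copy of it (the permuted baseline).
#' Reconstruction BCE and mean per-sample Pearson correlation are recorded
#' for both partitions; permuted-data models are evaluated on the real test
#' partition.  Individual fit failures are recorded and the grid continues.
#'
#' @param train,test min-max scaled samples x genes matrices.
#' @param algorithms subset of `r toString(BOMBE_ALGORITHMS)`.
#' @param k_grid latent dimensionalities to train.
#' @param seeds integer seeds, one model per seed.
#' @param include_permuted also train on gene-permuted training data.
#' @param permute_seed seed for the gene permutation.
#' @param ae_hyperparams passed to [fit_model()].
#' @return a `bombe_registry`: list with `$models` (keyed
#'   `algorithm|k|seed|data_tag`), `$metrics` (long data.frame), and
#'   `$failures`.
#' @export
run_grid <- function(train, test, algorithms = BOMBE_ALGORITHMS,
                     k_grid = default_k_grid(), seeds = 0:4,
                     include_permuted = TRUE, permute_seed = 0,
                     ae_hyperparams = list()) {
  algorithms <- match.arg(algorithms, BOMBE_ALGORITHMS, several.ok = TRUE)
  tags <- if (include_permuted) c("real", "permuted") else "real"
  train_sets <- list(real = train)
  if (include_permuted) {
    train_sets$permuted <- permute_within_genes(train, seed = permute_seed)
  }

  models <- list()
  metrics <- list()
  failures <- list()
  for (tag in tags) {
    tr <- train_sets[[tag]]
    for (alg in algorithms) {
      for (k in k_grid) {
        for (seed in seeds) {
          key <- model_key(alg, k, seed, tag)
          model <- tryCatch(
            fit_model(tr, alg, k, seed = seed,
                      ae_hyperparams = ae_hyperparams, data_tag = tag),
            error = function(e) e
          )
          if (inherits(model, "error")) {
            failures[[key]] <- conditionMessage(model)
            next
          }
          models[[key]] <- model
          for (split in c("train", "test")) {
            # permuted-data models are evaluated against real data too:
            # training metrics use the permuted matrix they saw, test
            # metrics use the real held-out partition
            dat <- if (split == "train") tr else test
            rec <- reconstruct(model, dat)
            metrics[[paste(key, split)]] <- data.frame(
              algorithm = alg, k = k, seed = seed, data_tag = tag,
              split = split,
              bce = reconstruction_bce(dat, rec),
              mean_pearson = mean(sample_pearson(dat, rec), na.rm = TRUE),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  registry <- list(models = models,
                   metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
                   failures = failures,
                   algorithms = algorithms, k_grid = as.integer(k_grid),
                   seeds = as.integer(seeds), data_tags = tags)
  class(registry) <- "bombe_registry"
  registry
}

#' @export
print.bombe_registry <- function(x, ...) {
  cat(sprintf("bombe_registry: %d models (%s; k = %s; %d seeds; %s)\n",
              length(x$models), toString(x$algorithms),
              toString(x$k_grid), length(x$seeds), toString(x$data_tags)))
  if (length(x$failures)) {
    cat(sprintf("  %d failed fits\n", length(x$failures)))
  }
  invisible(x)
}

#' Enumerate the size of a compression-grid configuration
#'
#' Pure arithmetic on a grid configuration: the number of fitted models and
#' the number of latent features they generate.  With the default grid (5
#' algorithms, 28 dimensionalities summing to 1234, 5 seeds, real plus
#' permuted data, 3 datasets) this gives 4200 models, 30,850 features per
#' dataset per data context, and 185,100 features in total.
#'
#' @param n_datasets number of datasets compressed.
#' @param algorithms algorithm names (or a count).
#' @param k_grid latent dimensionality grid.
#' @param n_seeds random initializations per configuration.
#' @param include_permuted whether a permuted-data copy of the grid is
#'   trained alongside the real one.
#' @return list with `n_models`, `features_per_dataset` (one data context),
#'   `total_features`, `n_dimensionalities`.
#' @export
grid_enumeration <- function(n_datasets = 3, algorithms = BOMBE_ALGORITHMS,
                             k_grid = default_k_grid(), n_seeds = 5,
                             include_permuted = TRUE) {
  n_alg <- if (is.numeric(algorithms)) algorithms else length(algorithms)
  n_tags <- if (include_permuted) 2L else 1L
  features_per_dataset <- sum(k_grid) * n_alg * n_seeds
  list(
    n_models = n_datasets * n_alg * length(k_grid) * n_seeds * n_tags,
    features_per_dataset = features_per_dataset,
    total_features = n_datasets * n_tags * features_per_dataset,
    n_dimensionalities = length(unique(k_grid))
  )
}
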