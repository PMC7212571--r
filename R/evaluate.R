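# Downstream evaluation of compressed features: transfer to external
# expression data, trait enrichment t-tests, alteration label construction,
# feature ensembles, and elastic-net classification.

#' Project learned weights onto an external expression dataset
#'
#' Transfers a representation to data measured on a (possibly) different
#' gene universe: the product is computed strictly over `g'`, the
#' intersection of the model genes and the external genes, with no
#' re-scaling of the external data (set `scale_external = TRUE` to min-max
#' scale it first).  The reported overlap fraction is `|g'| / |model
#' genes|`.
#'
#' @param weights genes x k weight matrix (or a single named column: one
#'   representation).
#' @param external samples x genes external expression matrix.
#' @param scale_external min-max scale the external data before the
#'   product.
#' @param min_overlap warn when the overlap fraction falls below this.
#' @return list of class `transfer_result` with `activations` (external
#'   samples x k), `shared_genes`, `overlap_fraction`.
#' @export
project_external <- function(weights, external, scale_external = FALSE,
                             min_overlap = 0.5) {
  if (is.null(dim(weights))) {
    weights <- matrix(weights, ncol = 1,
                      dimnames = list(names(weights), "feature_0"))
  }
  stop_if(is.null(rownames(weights)), "weights must have gene row names")
  check_expression(external)
  shared <- intersect(rownames(weights), colnames(external))
  stop_if(length(shared) == 0, "no genes shared with the external dataset")
  overlap <- length(shared) / nrow(weights)
  if (overlap < min_overlap) {
    warning(sprintf("only %.1f%% of model genes measured in external data",
                    100 * overlap))
  }
  if (scale_external) external <- minmax_scale(external)
  act <- external[, shared, drop = FALSE] %*% weights[shared, , drop = FALSE]
  structure(list(activations = act, shared_genes = shared,
                 overlap_fraction = overlap),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result: %d samples x %d features; %d shared genes (%.2f%%)\n",
              nrow(x$activations), ncol(x$activations),
              length(x$shared_genes), 100 * x$overlap_fraction))
  invisible(x)
}

#' Welch two-sample t-test on sample activation scores
#'
#' Two-tailed independent t-test assuming unequal variance
#' (Welch-Satterthwaite degrees of freedom), oriented as group 1 minus
#' group 0.
#'
#' @param scores numeric vector of per-sample activations.
#' @param labels binary group labels (0/1 or logical), same length.
#' @return list with `t`, `p`, `df`, `n1`, `n0`; all `NA` (with a warning)
#'   when either group is degenerate (fewer than two samples or zero
#'   variance).
#' @export
welch_ttest <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  x1 <- scores[labels == 1L]
  x0 <- scores[labels == 0L]
  if (length(x1) < 2 || length(x0) < 2 ||
      stats::sd(x1) == 0 && stats::sd(x0) == 0) {
    warning("degenerate group in welch_ttest(); returning NA")
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                n1 = length(x1), n0 = length(x0)))
  }
  res <- stats::t.test(x1, x0, var.equal = FALSE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), n1 = length(x1), n0 = length(x0))
}

#' Tissues with balanced sex representation
#'
#' Keeps tissues whose male-to-female sample count ratio lies in
#' \[0.5, 1.5\] (boundaries inclusive); tissues with zero samples of
#' either sex have an undefined or trivially extreme ratio and are
#' dropped.
#'
#' @param metadata data.frame with one row per sample.
#' @param tissue_col,sex_col metadata column names.
#' @param male,female values of `sex_col` coding the two groups.
#' @return character vector of retained tissue names.
#' @export
sex_balanced_strata <- function(metadata, tissue_col = "tissue",
                                sex_col = "sex", male = "male",
                                female = "female") {
  stop_if(!all(c(tissue_col, sex_col) %in% names(metadata)),
          "metadata must contain '", tissue_col, "' and '", sex_col, "'")
  kept <- character(0)
  for (tis in sort(unique(as.character(metadata[[tissue_col]])))) {
    rows <- metadata[[tissue_col]] == tis
    n_m <- sum(metadata[[sex_col]][rows] == male)
    n_f <- sum(metadata[[sex_col]][rows] == female)
    if (n_f == 0 || n_m == 0) next
    ratio <- n_m / n_f
    if (ratio >= 0.5 && ratio <= 1.5) kept <- c(kept, tis)
  }
  kept
}

#' Build binary gene-alteration labels with cohort filters
#'
#' A sample is positive when it carries a non-silent mutation in the gene,
#' or a high-level copy-number event of the class matching the gene's role
#' (amplification, GISTIC score +2, for oncogenes; deep deletion, score
#' -2, for tumor suppressors).  Hypermutators -- samples whose log10
#' mutation count exceeds the cohort mean by five standard deviations --
#' are removed before any class balance check.  Cancer types are then kept
#' only if their positive-class fraction lies in \[0.05, 0.95\] and both
#' classes have at least 15 samples.
#'
#' @param mutated logical/0-1 vector per sample: non-silent mutation in the
#'   gene.
#' @param copy_calls integer GISTIC-style calls per sample (-2..2).
#' @param cancer_type character/factor per sample.
#' @param burden per-sample total mutation counts.
#' @param gene_class `"oncogene"` or `"tsg"`.
#' @return list of class `alteration_labels` with `labels` (named 0/1
#'   vector over retained samples), `included_types`, `excluded`
#'   (data.frame log of removed samples/types and the reason).
#' @export
build_alteration_labels <- function(mutated, copy_calls, cancer_type, burden,
                                    gene_class = c("oncogene", "tsg")) {
  gene_class <- match.arg(gene_class)
  n <- length(mutated)
  stopifnot(length(copy_calls) == n, length(cancer_type) == n,
            length(burden) == n)
  ids <- names(mutated)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  copy_hit <- if (gene_class == "oncogene") copy_calls == 2 else copy_calls == -2
  status <- as.integer(as.logical(mutated) | copy_hit)
  names(status) <- ids

  excluded <- list()
  log_burden <- log10(pmax(burden, 1))
  hyper <- log_burden > mean(log_burden) + 5 * stats::sd(log_burden)
  if (any(hyper)) {
    excluded[[length(excluded) + 1L]] <- data.frame(
      what = ids[hyper], reason = "hypermutator", stringsAsFactors = FALSE)
  }
  keep <- !hyper
  status <- status[keep]
  cancer_type <- as.character(cancer_type)[keep]

  included_types <- character(0)
  for (ct in sort(unique(cancer_type))) {
    s <- status[cancer_type == ct]
    frac <- mean(s)
    n_pos <- sum(s == 1L)
    n_neg <- sum(s == 0L)
    if (frac < 0.05 || frac > 0.95) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        what = ct, reason = sprintf("class fraction %.3f outside [0.05, 0.95]", frac),
        stringsAsFactors = FALSE)
    } else if (n_pos < 15 || n_neg < 15) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        what = ct, reason = sprintf("class sizes %d/%d below 15", n_pos, n_neg),
        stringsAsFactors = FALSE)
    } else {
      included_types <- c(included_types, ct)
    }
  }
  sel <- cancer_type %in% included_types
  structure(list(labels = status[sel],
                 cancer_type = cancer_type[sel],
                 included_types = included_types,
                 excluded = if (length(excluded)) {
                   do.call(rbind, c(excluded, make.row.names = FALSE))
                 } else {
                   data.frame(what = character(), reason = character())
                 }),
            class = "alteration_labels")
}

#' Column-concatenated feature matrices from ensembles of models
#'
#' Builds a samples x features activation matrix by pooling models from
#' the registry: a single model, the five seeds of the VAE at one
#' dimensionality, one seed of every algorithm at one dimensionality, or
#' every model in the registry.  Column names encode
#' `algorithm_k<k>_s<seed>_<feature>`.
#'
#' @param registry a `bombe_registry`.
#' @param data samples x genes matrix to transform (training gene
#'   universe).
#' @param mode `"single"`, `"vae_5seed"`, `"one_seed_all_algorithms"`, or
#'   `"all_features"`.
#' @param k latent dimensionality (modes other than `all_features`).
#' @param seed seed selecting the model (`single`,
#'   `one_seed_all_algorithms`).
#' @param algorithm algorithm for `single` mode.
#' @param data_tag data context of the pooled models.
#' @return samples x features numeric matrix.
#' @export
build_ensemble_features <- function(registry, data,
                                    mode = c("single", "vae_5seed",
                                             "one_seed_all_algorithms",
                                             "all_features"),
                                    k = NULL, seed = NULL, algorithm = NULL,
                                    data_tag = "real") {
  stopifnot(inherits(registry, "bombe_registry"))
  mode <- match.arg(mode)
  keys <- switch(mode,
    single = model_key(algorithm, k, seed, data_tag),
    vae_5seed = vapply(registry$seeds, function(s) model_key("vae", k, s, data_tag),
                       character(1)),
    one_seed_all_algorithms = vapply(registry$algorithms,
                                     function(a) model_key(a, k, seed, data_tag),
                                     character(1)),
    all_features = {
      tagged <- grepl(paste0("\\|", data_tag, "$"), names(registry$models))
      names(registry$models)[tagged]
    }
  )
  missing_keys <- setdiff(keys, names(registry$models))
  stop_if(length(missing_keys) > 0,
          "registry is missing model(s): ", toString(missing_keys))
  blocks <- lapply(keys, function(key) {
    m <- registry$models[[key]]
    act <- predict(m, data)
    colnames(act) <- sprintf("%s_k%d_s%d_%s", m$algorithm, m$k, m$seed,
                             colnames(act))
    act
  })
  do.call(cbind, blocks)
}

#' Elastic-net logistic regression over a hyperparameter grid
#'
#' Grid search over regularization strength (`lambda`) and elastic-net
#' mixing (`mixing`; 0 = ridge, 1 = lasso) by stratified k-fold
#' cross-validated AUROC, refitting the winning combination on all data.
#' The default grid is lambda in \{0.1, 0.13, 0.15, 0.2, 0.25, 0.3\} and
#' mixing in \{0.15, 0.16, 0.2, 0.25, 0.3, 0.4\} (36 combinations).
#' Optional covariates (e.g. log10 mutation burden, one-hot cancer type)
#' are appended unpenalized (`penalty.factor = 0`).
#'
#' @param features samples x features numeric matrix.
#' @param labels binary labels (0/1 or logical).
#' @param covariates optional samples x q matrix appended unpenalized.
#' @param cv_folds number of stratified folds.
#' @param lambdas,mixings hyperparameter grids.
#' @param seed fold-assignment seed.
#' @param min_class_size minimum samples per class.
#' @return list of class `elasticnet_result` with `fit` (the refit glmnet
#'   model), `best` (chosen lambda/mixing), `cv_auroc`, `cv_aupr`,
#'   `cv_metrics` (full grid), `n_nonzero`, `sparsity` (fraction of zero
#'   feature coefficients).
#' @export
train_elasticnet <- function(features, labels, covariates = NULL,
                             cv_folds = 5,
                             lambdas = c(0.1, 0.13, 0.15, 0.2, 0.25, 0.3),
                             mixings = c(0.15, 0.16, 0.2, 0.25, 0.3, 0.4),
                             seed = 0, min_class_size = 15) {
  labels <- as.integer(as.logical(labels))
  stop_if(length(unique(labels)) < 2, "labels must contain both classes")
  stop_if(min(table(labels)) < min_class_size,
          "each class needs at least ", min_class_size, " samples")
  x <- as.matrix(features)
  n_feat <- ncol(x)
  pf <- rep(1, n_feat)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    x <- cbind(x, covariates)
    pf <- c(pf, rep(0, ncol(covariates)))
  }

  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  })

  cv_rows <- list()
  for (mix in mixings) {
    # one glmnet path per (fold, mixing); individual lambdas read off it
    preds <- matrix(NA_real_, length(labels), length(lambdas))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], labels[tr],
                            family = "binomial", alpha = mix,
                            lambda = lambdas, penalty.factor = pf,
                            standardize = TRUE)
      preds[!tr, ] <- stats::predict(fit, x[!tr, , drop = FALSE],
                                     s = lambdas, type = "response")
    }
    for (li in seq_along(lambdas)) {
      cv_rows[[length(cv_rows) + 1L]] <- data.frame(
        lambda = lambdas[li], mixing = mix,
        cv_auroc = auroc(preds[, li], labels),
        cv_aupr = aupr(preds[, li], labels)
      )
    }
  }
  cv_metrics <- do.call(rbind, cv_rows)
  best <- cv_metrics[which.max(cv_metrics$cv_auroc), ]

  fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = best$mixing,
                        lambda = lambdas, penalty.factor = pf,
                        standardize = TRUE)
  coefs <- as.numeric(stats::coef(fit, s = best$lambda))[-1][seq_len(n_feat)]
  structure(list(fit = fit, best = best,
                 cv_auroc = best$cv_auroc, cv_aupr = best$cv_aupr,
                 cv_metrics = cv_metrics,
                 n_nonzero = sum(coefs != 0),
                 sparsity = mean(coefs == 0),
                 feature_coefficients = stats::setNames(coefs, colnames(features))),
            class = "elasticnet_result")
}

#' @export
print.elasticnet_result <- function(x, ...) {
  cat(sprintf("elasticnet: CV AUROC %.3f, AUPR %.3f (lambda %.3g, mixing %.3g); %d/%d non-zero\n",
              x$cv_auroc, x$cv_aupr, x$best$lambda, x$best$mixing,
              x$n_nonzero, length(x$feature_coefficients)))
  invisible(x)
}

#' Average AUPR change between real-data and permuted-data models
#'
#' Matches rows of the two metric tables on the given keys and averages
#' `aupr_real - aupr_permuted` over tasks; unmatched keys are skipped with
#' a message.
#'
#' @param metrics_real,metrics_permuted data.frames each containing the key
#'   columns and an `aupr` column.
#' @param keys key columns to match on.
#' @return scalar mean AUPR difference.
#' @export
aupr_delta <- function(metrics_real, metrics_permuted,
                       keys = intersect(names(metrics_real), c("task", "algorithm", "k"))) {
  merged <- merge(metrics_real, metrics_permuted, by = keys,
                  suffixes = c("_real", "_permuted"))
  skipped <- nrow(metrics_real) - nrow(merged)
  if (skipped > 0) message(skipped, " unmatched key(s) skipped")
  stop_if(nrow(merged) == 0, "no matching keys between the two tables")
  mean(merged$aupr_real - merged$aupr_permuted)
}
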