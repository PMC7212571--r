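test_that("external projection restricts to the shared gene universe", {
  W <- fit_model(tiny_train, "pca", k = 3, seed = 0)$W

  full <- project_external(W, tiny_test)
  expect_equal(full$overlap_fraction, 1.0)
  expect_equal(full$activations, tiny_test %*% W)

  subset_genes <- colnames(tiny_test)[1:150]
  partial <- suppressWarnings(
    project_external(W, tiny_test[, subset_genes]))
  expect_equal(partial$overlap_fraction, 0.5)
  # zeroing missing-gene weights and multiplying over the full universe
  # gives the identical restricted product
  W0 <- W
  W0[!rownames(W) %in% subset_genes, ] <- 0
  expect_equal(partial$activations, tiny_test %*% W0, tolerance = 1e-12)

  other <- tiny_test
  colnames(other) <- paste0("x", colnames(other))
  expect_error(project_external(W, other), "no genes shared")

  # single representation column
  one <- project_external(W[, 1], tiny_test)
  expect_equal(ncol(one$activations), 1L)
})

test_that("Welch t-test matches the hand computation and is orientation-aware", {
  scores <- c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6)
  labels <- rep(c(1, 0), each = 5)
  res <- welch_ttest(scores, labels)
  expect_equal(res$t, -1.0, tolerance = 1e-12)      # sd^2 = 2.5 each, se = 1
  expect_equal(res$df, 8, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-1, 8), tolerance = 1e-12)
  expect_equal(res$p, 0.347, tolerance = 2e-3)

  flipped <- welch_ttest(scores, 1 - labels)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p, res$p)

  same <- welch_ttest(rep(c(1, 2, 3), 2), rep(c(1, 0), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_warning(bad <- welch_ttest(c(1, 2, 3), c(1, 0, 0)), "degenerate")
  expect_true(is.na(bad$t))
})

test_that("sex-balanced strata use the inclusive 0.5-1.5 ratio rule", {
  metadata <- data.frame(
    tissue = rep(c("even", "skewed", "edge", "nofem"), c(20, 14, 25, 5)),
    sex = c(rep(c("male", "female"), 10),     # 10M/10F ratio 1.0
            rep(c("male", "female"), c(4, 10)), # ratio 0.4
            rep(c("male", "female"), c(15, 10)), # ratio 1.5, boundary
            rep("male", 5))                   # zero females
  )
  expect_setequal(sex_balanced_strata(metadata), c("even", "edge"))
})

test_that("alteration labels apply mutation/copy logic and cohort filters", {
  n_a <- 100; n_b <- 50; n_c <- 40
  type <- rep(c("A", "B", "C"), c(n_a, n_b, n_c))
  ids <- sprintf("s%03d", seq_along(type))
  mutated <- setNames(rep(0L, length(type)), ids)
  mutated[type == "A"][1:3] <- 1L                   # 3% positive -> excluded
  mutated[type == "B"][1:15] <- 1L
  mutated[type == "C"][1:10] <- 1L                  # 10 positives < 15 -> excluded
  copy <- rep(0L, length(type))
  copy[type == "B"][16:20] <- 2L                    # amplifications add positives
  burden <- rep(100, length(type))
  burden[1] <- 1e10                                 # hypermutator in type A

  labs <- build_alteration_labels(mutated, copy, type, burden,
                                  gene_class = "oncogene")
  expect_equal(labs$included_types, "B")
  expect_equal(sum(labs$labels), 20)                 # 15 mutations + 5 amps
  expect_false("s001" %in% names(labs$labels))
  expect_true("s001" %in% labs$excluded$what)
  expect_true(any(grepl("hypermutator", labs$excluded$reason)))
  expect_true(any(grepl("0.05", labs$excluded$reason)))   # type A fraction
  expect_true(any(grepl("below 15", labs$excluded$reason)))  # type C sizes

  # deep deletions only count for tumor suppressors
  del <- rep(0L, length(type)); del[type == "B"][16:20] <- -2L
  tsg <- build_alteration_labels(mutated, del, type, burden, gene_class = "tsg")
  expect_equal(sum(tsg$labels), 20)
  onc <- build_alteration_labels(mutated, del, type, burden, gene_class = "oncogene")
  expect_equal(sum(onc$labels), 15)
})

test_that("ensemble feature matrices concatenate the requested models", {
  hp <- list(epochs = 2)
  reg <- run_grid(tiny_train, tiny_test,
                  algorithms = c("pca", "ica", "nmf", "dae", "vae"),
                  k_grid = c(3, 4), seeds = 0:4, include_permuted = FALSE,
                  ae_hyperparams = hp)
  vae5 <- build_ensemble_features(reg, tiny_test, mode = "vae_5seed", k = 4)
  expect_equal(ncol(vae5), 20)

  one_all <- build_ensemble_features(reg, tiny_test,
                                     mode = "one_seed_all_algorithms",
                                     k = 3, seed = 0)
  expect_equal(ncol(one_all), 15)

  all_feat <- build_ensemble_features(reg, tiny_test, mode = "all_features")
  expect_equal(ncol(all_feat), (3 + 4) * 5 * 5)
  expect_equal(nrow(all_feat), nrow(tiny_test))

  expect_error(build_ensemble_features(reg, tiny_test, mode = "single",
                                       algorithm = "pca", k = 99, seed = 0),
               "missing model")
})

test_that("elastic net separates a feature-defined label near perfectly", {
  with_seed(21, x <- matrix(rnorm(200 * 10), 200, 10))
  colnames(x) <- paste0("f", 1:10)
  y <- as.integer(x[, 1] > median(x[, 1]))
  res <- train_elasticnet(x, y, seed = 1)
  expect_gt(res$cv_auroc, 0.95)
  expect_equal(nrow(res$cv_metrics), 36)  # 6 lambdas x 6 mixing values

  expect_error(train_elasticnet(x, rep(1, 200)), "both classes")
  expect_error(train_elasticnet(x[1:20, ], y[1:20]), "at least 15")
})

test_that("higher l1 mixing is sparser on redundant duplicated features", {
  with_seed(33, base <- matrix(rnorm(150 * 5), 150, 5))
  x <- cbind(base, base)  # every feature duplicated
  colnames(x) <- paste0("f", 1:10)
  y <- as.integer(base[, 1] + base[, 2] > 0)
  high_l1 <- train_elasticnet(x, y, lambdas = 0.1, mixings = 0.95, seed = 2)
  low_l1 <- train_elasticnet(x, y, lambdas = 0.1, mixings = 0.01, seed = 2)
  expect_lt(high_l1$n_nonzero, low_l1$n_nonzero)
})

test_that("unpenalized covariates survive heavy regularization", {
  with_seed(41, {
    x <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("f", 1:5)))
    cov1 <- rnorm(120)
  })
  y <- as.integer(cov1 + rnorm(120, sd = 0.3) > 0)
  res <- train_elasticnet(x, y, covariates = cbind(burden = cov1),
                          lambdas = 0.3, mixings = 0.4, seed = 3)
  full_coefs <- as.numeric(coef(res$fit, s = 0.3))
  expect_gt(abs(full_coefs[length(full_coefs)]), 0)  # covariate kept
})

test_that("AUPR deltas are zero on identical inputs and antisymmetric", {
  real <- data.frame(task = c("a", "b"), algorithm = "pca", k = 3,
                     aupr = c(0.8, 0.9))
  perm <- data.frame(task = c("a", "b"), algorithm = "pca", k = 3,
                     aupr = c(0.5, 0.4))
  expect_equal(aupr_delta(real, real), 0)
  expect_equal(aupr_delta(real, perm), -aupr_delta(perm, real))
  expect_equal(aupr_delta(real, perm), mean(c(0.3, 0.5)))
  unmatched <- data.frame(task = "c", algorithm = "pca", k = 3, aupr = 1)
  expect_error(suppressMessages(aupr_delta(real, unmatched)), "no matching")
})

test_that("rank-based AUROC agrees with the ROC-curve integral", {
  skip_if_not_installed("pROC")
  with_seed(55, {
    scores <- rnorm(100)
    labels <- as.integer(scores + rnorm(100) > 0)
  })
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-10)
  perfect <- auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(perfect, 1)
  expect_equal(aupr(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
})
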