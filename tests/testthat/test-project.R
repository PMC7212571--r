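mk_scores <- function(Z, p = NULL) {
  if (is.null(p)) p <- 2 * pnorm(-abs(Z))
  structure(list(Z = Z, p = p), class = "bombe_scores")
}

test_that("raw projection scores are the membership-weight product", {
  H1 <- matrix(1, 1, 3, dimnames = list("all", c("g1", "g2", "g3")))
  W <- matrix(c(0.5, -0.2, 0.7), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "feature_0"))
  expect_equal(as.numeric(raw_scores(H1, W)), 1.0)

  H <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
              dimnames = list(c("A", "B"), c("g1", "g2", "g3")))
  Wc <- matrix(1:3, 3, 1, dimnames = list(c("g1", "g2", "g3"), "feature_0"))
  expect_equal(as.numeric(raw_scores(H, Wc)), c(3, 5))

  empty <- rbind(H, C = c(0, 0, 0))
  expect_equal(as.numeric(raw_scores(empty, Wc)["C", ]), 0)

  expect_error(raw_scores(H, Wc[c(2, 1, 3), , drop = FALSE]), "gene order")

  # linearity in W
  with_seed(2, {
    W1 <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
    W2 <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
  })
  expect_equal(raw_scores(H, 2 * W1 + 3 * W2),
               2 * raw_scores(H, W1) + 3 * raw_scores(H, W2))
})

test_that("z-scores use the population sd of the permuted scores", {
  as_cell <- function(v) matrix(v, 1, 1, dimnames = list("s", "f"))
  sc <- zscores(as_cell(2), lapply(c(1, 2, 3), as_cell))
  expect_equal(as.numeric(sc$Z), 0)
  expect_equal(as.numeric(sc$p), 1)

  sc <- zscores(as_cell(2.4), lapply(c(0, 0, 0, 0, 2), as_cell))
  expect_equal(as.numeric(sc$Z), 2.5)  # population sd 0.8 around mean 0.4

  sc <- zscores(as_cell(1.959964), lapply(c(-1, 1, -1, 1), as_cell))
  expect_equal(as.numeric(sc$p), 0.05, tolerance = 1e-6)

  # zero permuted sd: z = 0 when observed equals the mean, undefined otherwise
  sc <- zscores(as_cell(5), lapply(c(5, 5, 5), as_cell))
  expect_equal(as.numeric(sc$Z), 0)
  sc <- zscores(as_cell(6), lapply(c(5, 5, 5), as_cell))
  expect_true(is.na(as.numeric(sc$Z)))
})

test_that("matrix z-score engine matches the per-cell loop oracle", {
  with_seed(31, {
    G <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(paste0("set", 1:8), paste0("f", 1:6)))
    perms <- lapply(1:10, function(i) {
      P <- matrix(rnorm(8 * 6), 8, 6, dimnames = dimnames(G))
      P[1, 1] <- 0  # force one constant cell across permutations
      P
    })
  })
  G[1, 1] <- 0
  sc <- zscores(G, perms)
  expect_equal(sc$Z, zscore_loop_oracle(G, perms), tolerance = 1e-12)
})

test_that("top assignment takes one set per tail and applies Bonferroni", {
  Z <- matrix(c(5, -6, 0.1), 3, 1,
              dimnames = list(c("set1", "set2", "set3"), "f1"))
  top <- assign_top(mk_scores(Z), alpha_base = 0.05, n_latent_dims = 3)
  expect_equal(top$set[top$tail == "pos"], "set1")
  expect_equal(top$set[top$tail == "neg"], "set2")
  expect_true(all(top$passed))

  weak <- assign_top(mk_scores(Z / 10), alpha_base = 0.05, n_latent_dims = 3)
  expect_false(any(weak$passed))

  # tie in max z broken by lexicographically smallest set name
  tied <- matrix(c(4, 4, -4), 3, 1,
                 dimnames = list(c("zeta", "alpha", "omega"), "f1"))
  top <- assign_top(mk_scores(tied), n_latent_dims = 1)
  expect_equal(top$set[top$tail == "pos"], "alpha")

  # undefined z never assigned
  nas <- matrix(c(NA, 3, -3), 3, 1,
                dimnames = list(c("set1", "set2", "set3"), "f1"))
  top <- assign_top(mk_scores(nas, p = 2 * pnorm(-abs(nas))), n_latent_dims = 1)
  expect_false("set1" %in% top$set)
})

test_that("coverage is the unique captured fraction of the collection", {
  one_set <- data.frame(feature = paste0("f", 1:10), set = "only",
                        z = 5, p = 1e-8, tail = "pos", passed = TRUE)
  expect_equal(coverage(one_set, 50)$coverage, 0.02)

  three <- data.frame(feature = rep(paste0("f", 1:3), each = 2),
                      set = paste0("s", 1:6), z = 5, p = 1e-8,
                      tail = rep(c("pos", "neg"), 3), passed = TRUE)
  expect_equal(coverage(three, 8)$coverage, 0.75)

  # pooling models: ensemble coverage >= any individual coverage
  a <- three[1:2, ]
  b <- three[3:6, ]
  expect_gte(coverage(list(a, b), 8)$coverage,
             max(coverage(a, 8)$coverage, coverage(b, 8)$coverage))
  expect_error(coverage(three, 0), "positive")
})

test_that("Fisher overrepresentation matches the exact test", {
  # weights engineered so the high tail is exactly the 10 high-value genes
  w <- setNames(c(rep(10, 10), rep(0, 10)), paste0("g", 1:20))
  bg <- names(w)

  balanced <- ora_fisher(w, geneset = paste0("g", c(1:5, 11:15)), bg,
                         sd_cutoff = 0, tail = "high")
  expect_equal(balanced$odds_ratio, 1)
  expect_equal(balanced$p_value, 1)

  enriched <- ora_fisher(w, geneset = paste0("g", c(1:8, 11:12)), bg,
                         sd_cutoff = 0, tail = "high")
  expect_equal(enriched$odds_ratio, 16)  # (8*8)/(2*2)
  expect_equal(enriched$p_value,
               fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value)
  expect_equal(enriched$p_value, 0.023, tolerance = 1e-3)

  expect_warning(none <- ora_fisher(w, geneset = "g99", bg), "no overlap")
  expect_true(is.na(none$odds_ratio))

  # tail beyond the data: empty tail, p = 1
  empty <- ora_fisher(w, geneset = paste0("g", 1:5), bg,
                      sd_cutoff = 10, tail = "high")
  expect_equal(empty$p_value, 1)
  expect_equal(empty$n_tail, 0L)
})

test_that("decoy-only collections yield calibrated null z-scores", {
  universe <- paste0("g", 1:200)
  with_seed(17, {
    sets <- lapply(1:30, function(i) sample(universe, 15))
    names(sets) <- sprintf("decoy%02d", 1:30)
    W <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(universe, paste0("f", 1:5)))
  })
  H <- build_membership(gene_set_collection(sets), universe)
  ens <- permuted_ensemble(H, n_permutations = 10, base_seed = 23)
  sc <- zscores(raw_scores(H, W), ens, W = W)
  z <- sc$Z[!is.na(sc$Z)]
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.7)
  expect_lt(sd(z), 1.3)
})

test_that("planted sets are the top assignments on synthetic data", {
  ens <- permuted_ensemble(tiny_H, n_permutations = 10, base_seed = 5)
  m <- fit_model(tiny_train, "pca", k = 4, seed = 0)
  sc <- zscores(raw_scores(tiny_H, m$W), ens, W = m$W)
  top <- assign_top(sc, n_latent_dims = 4)
  captured <- intersect(top$set[top$passed],
                        names(tiny_sim$truth$planted_sets))
  expect_setequal(captured, names(tiny_sim$truth$planted_sets))
})
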