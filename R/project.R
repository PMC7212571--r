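# Network projection of gene-set membership onto compression weight
# matrices: raw scores, z-scores against the XSwap permutation null,
# significance-filtered top assignments, coverage, and the Fisher-exact
# overrepresentation baseline.

#' Raw gene-set projection scores
#'
#' A single matrix multiplication `G = H %*% W` scores every gene set
#' (rows of the membership matrix H) against every latent feature (columns
#' of the weight matrix W).
#'
#' @param H gene-sets x genes binary membership matrix.
#' @param W genes x k weight matrix; `rownames(W)` must equal
#'   `colnames(H)` (callers align the gene order).
#' @return gene-sets x features score matrix.
#' @export
raw_scores <- function(H, W) {
  stop_if(is.null(colnames(H)) || is.null(rownames(W)) ||
            !identical(colnames(H), rownames(W)),
          "gene order mismatch between H columns and W rows")
  H %*% W
}

#' Z-score projection scores against the permuted-network null
#'
#' For each (gene set, feature) cell, the observed raw score is compared to
#' the distribution of scores obtained with the degree-preserving permuted
#' networks: `z = (G - mean(G_p)) / sd(G_p)`, with the population standard
#' deviation (divisor n) over the permutation values per cell.  Two-tailed
#' normal p-values accompany each z.  Cells where the permuted sd is zero
#' get z = 0 when the observed score equals the permuted mean and are
#' flagged undefined (NA) otherwise; undefined cells never enter top
#' assignments or coverage.
#'
#' @param G observed raw score matrix from [raw_scores()].
#' @param ensemble either a `permuted_ensemble` (scores are computed
#'   against `W`) or a list of pre-computed permuted raw-score matrices.
#' @param W weight matrix, required when `ensemble` is a
#'   `permuted_ensemble`.
#' @return list of class `bombe_scores` with `Z`, `p`, `perm_mean`,
#'   `perm_sd` (all gene-sets x features).
#' @export
zscores <- function(G, ensemble, W = NULL) {
  if (inherits(ensemble, "permuted_ensemble")) {
    stop_if(is.null(W), "W is required to score a permuted_ensemble")
    perm_scores <- lapply(ensemble$permutations, raw_scores, W = W)
  } else {
    perm_scores <- ensemble
  }
  stop_if(length(perm_scores) < 2, "need at least 2 permuted score matrices")
  for (P in perm_scores) {
    stop_if(!identical(dim(P), dim(G)), "permuted score matrix shape mismatch")
  }
  n <- length(perm_scores)
  perm_mean <- Reduce(`+`, perm_scores) / n
  perm_var <- Reduce(`+`, lapply(perm_scores, function(P) (P - perm_mean)^2)) / n
  perm_sd <- sqrt(perm_var)

  Z <- (G - perm_mean) / perm_sd
  zero_sd <- perm_sd == 0
  Z[zero_sd & (G == perm_mean)] <- 0
  Z[zero_sd & (G != perm_mean)] <- NA_real_
  p <- 2 * stats::pnorm(-abs(Z))
  structure(list(Z = Z, p = p, perm_mean = perm_mean, perm_sd = perm_sd),
            class = "bombe_scores")
}

#' Top gene-set assignment per latent feature
#'
#' A gene set is "captured" by a feature if it has the highest positive or
#' the highest negative z-score among all sets in the collection for that
#' feature, and its p-value passes a Bonferroni threshold
#' `alpha_base / n_latent_dims` (the divisor is the total number of latent
#' dimensionalities in the model).  Each feature can contribute up to two
#' captured sets, one per tail.  Ties are broken by lexicographic set name.
#'
#' @param scores a `bombe_scores` object from [zscores()].
#' @param alpha_base base significance level for the Bonferroni rule.
#' @param n_latent_dims Bonferroni divisor; defaults to the number of
#'   features (columns of Z).
#' @return data.frame with columns `feature`, `set`, `z`, `p`, `tail`
#'   (pos/neg), `passed` (Bonferroni flag); only rows describing the
#'   extreme set in each tail are present.
#' @export
assign_top <- function(scores, alpha_base = 0.05, n_latent_dims = NULL) {
  stopifnot(inherits(scores, "bombe_scores"))
  Z <- scores$Z
  p <- scores$p
  if (is.null(n_latent_dims)) n_latent_dims <- ncol(Z)
  threshold <- alpha_base / n_latent_dims
  set_names <- rownames(Z)
  rows <- list()
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    ok <- !is.na(z)
    if (!any(ok)) next
    for (tail in c("pos", "neg")) {
      extreme <- if (tail == "pos") max(z[ok]) else min(z[ok])
      if ((tail == "pos" && extreme <= 0) || (tail == "neg" && extreme >= 0)) next
      # ties broken by lexicographically smallest set name
      idx <- which(ok & z == extreme)[order(set_names[ok & z == extreme])][1L]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = colnames(Z)[j], set = set_names[idx],
        z = z[idx], p = p[idx, j], tail = tail,
        passed = p[idx, j] < threshold, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), set = character(), z = numeric(),
               p = numeric(), tail = character(), passed = logical())
  attr(out, "alpha_base") <- alpha_base
  attr(out, "n_latent_dims") <- n_latent_dims
  out
}

#' Gene-set coverage of a collection by compressed features
#'
#' Coverage `C = U_w / T_c`: the number of unique gene sets captured (as a
#' Bonferroni-passing top assignment of at least one feature) divided by
#' the collection size.  Pass the pooled assignments of whatever model
#' grouping is of interest: a single model (individual coverage), all seeds
#' of one algorithm (ensemble coverage), all models at one dimensionality,
#' or everything combined.
#'
#' @param assignments one assignment data.frame from [assign_top()], or a
#'   list of them to pool (union).
#' @param collection_size total number of gene sets in the collection
#'   (T_c).
#' @return list with `captured_sets` (sorted unique names), `n_captured`,
#'   `collection_size`, `coverage`.
#' @export
coverage <- function(assignments, collection_size) {
  stop_if(collection_size <= 0, "collection_size must be positive")
  if (is.data.frame(assignments)) assignments <- list(assignments)
  captured <- sort(unique(unlist(lapply(assignments, function(a) {
    a$set[a$passed]
  }))))
  list(captured_sets = captured, n_captured = length(captured),
       collection_size = collection_size,
       coverage = length(captured) / collection_size)
}

#' Fisher exact overrepresentation test on one feature's gene weights
#'
#' The comparison baseline for network projection: genes in the selected
#' tail of the weight distribution (more than `sd_cutoff` standard
#' deviations above the mean for the high tail; below for the low tail)
#' are tested for overlap with a gene set via Fisher's exact test.  The
#' background is the set of genes represented in the gene-set collection
#' under study, intersected with the weight vector's genes.
#'
#' @param weights named numeric vector: one feature column of W.
#' @param geneset character vector of gene IDs.
#' @param background character vector of background gene IDs.
#' @param sd_cutoff tail threshold in standard deviations.
#' @param tail `"high"` or `"low"`.
#' @return list with `odds_ratio` (cross-product ratio (a d)/(b c)),
#'   `p_value` (two-sided exact), `table` (2x2 contingency), `n_tail`.
#' @export
ora_fisher <- function(weights, geneset, background, sd_cutoff = 2,
                       tail = c("high", "low")) {
  tail <- match.arg(tail)
  stop_if(length(background) == 0, "background must be nonempty")
  stop_if(is.null(names(weights)), "weights must be named by gene ID")
  background <- unique(as.character(background))
  background <- background[background %in% names(weights)]
  geneset <- unique(as.character(geneset))
  geneset <- geneset[geneset %in% background]
  if (length(geneset) == 0) {
    warning("gene set has no overlap with the background; excluded")
    return(list(odds_ratio = NA_real_, p_value = NA_real_,
                table = NULL, n_tail = NA_integer_))
  }
  w <- weights[background]
  cut <- mean(w) + sd_cutoff * stats::sd(w) * (if (tail == "high") 1 else -1)
  in_tail <- if (tail == "high") w > cut else w < cut
  if (!any(in_tail)) {
    return(list(odds_ratio = NA_real_, p_value = 1,
                table = table(factor(in_tail, c(TRUE, FALSE)),
                              factor(background %in% geneset, c(TRUE, FALSE))),
                n_tail = 0L))
  }
  in_set <- background %in% geneset
  a <- sum(in_tail & in_set); b <- sum(in_tail & !in_set)
  c_ <- sum(!in_tail & in_set); d <- sum(!in_tail & !in_set)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(tail = c("in", "out"), set = c("in", "out")))
  odds_ratio <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = odds_ratio, p_value = p, table = tab,
       n_tail = sum(in_tail))
}
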