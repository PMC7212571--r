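# SVCCA: singular vector canonical correlation analysis between weight
# matrices.  SVD reduces each matrix to the leading directions carrying a
# fixed share of its signal; CCA then aligns the two reduced
# representations, and the mean canonical correlation summarizes their
# similarity.  Used to measure model stability across random
# initializations and similarity across algorithms and dimensionalities.

inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

svd_reduce <- function(W, variance_threshold, center, squared) {
  if (center) W <- sweep(W, 2, colMeans(W), "-")
  sv <- svd(W)
  crit <- if (squared) sv$d^2 else sv$d
  total <- sum(crit)
  stop_if(total == 0, "weight matrix has rank 0")
  d <- which(cumsum(crit) / total >= variance_threshold - 1e-12)[1]
  d <- max(d, 1L)
  list(X = sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], d),
       retained = d)
}

#' SVCCA similarity between two weight matrices
#'
#' Each genes x features weight matrix is column-centered and reduced by
#' SVD to the smallest leading set of directions whose squared singular
#' values sum to at least `variance_threshold` of the total (set
#' `squared = FALSE` to threshold on raw singular values instead).  CCA is
#' then computed between the two reduced representations over genes, and
#' the mean of the canonical correlations is returned.  The result is
#' invariant to invertible linear maps of either matrix's feature space,
#' which is what makes it a fair comparison between algorithms whose
#' features have no inherent order or scale.
#'
#' @param W1,W2 genes x features matrices sharing the same gene rows.
#' @param variance_threshold share of signal the SVD step retains.
#' @param center column-center the weight matrices first (standard SVCCA
#'   preprocessing).
#' @param squared threshold cumulative squared singular values (variance)
#'   rather than raw singular values.
#' @param ridge regularization added to the covariance diagonals for
#'   conditioning.
#' @return object of class `svcca_result`: list with `mean_cc`,
#'   `correlations` (length `min(retained_dims)`), `retained_dims`,
#'   `variance_threshold`.
#' @export
svcca <- function(W1, W2, variance_threshold = 0.98, center = TRUE,
                  squared = TRUE, ridge = 1e-10) {
  stop_if(nrow(W1) != nrow(W2), "weight matrices must share gene rows")
  r1 <- svd_reduce(W1, variance_threshold, center, squared)
  r2 <- svd_reduce(W2, variance_threshold, center, squared)
  X <- r1$X
  Y <- r2$X
  n <- nrow(X)
  Sxx <- crossprod(X) / (n - 1)
  Syy <- crossprod(Y) / (n - 1)
  # regularization scaled to the covariance magnitude, so conditioning
  # support does not bias canonical correlations on well-posed inputs
  Sxx <- Sxx + diag(ridge * mean(diag(Sxx)), ncol(X))
  Syy <- Syy + diag(ridge * mean(diag(Syy)), ncol(Y))
  Sxy <- crossprod(X, Y) / (n - 1)
  M <- inv_sqrt(Sxx) %*% Sxy %*% inv_sqrt(Syy)
  cc <- svd(M)$d[seq_len(min(ncol(X), ncol(Y)))]
  cc <- pmin(pmax(cc, 0), 1)
  structure(list(mean_cc = mean(cc), correlations = cc,
                 retained_dims = c(r1$retained, r2$retained),
                 variance_threshold = variance_threshold),
            class = "svcca_result")
}

#' @export
print.svcca_result <- function(x, ...) {
  cat(sprintf("svcca: mean canonical correlation %.4f (retained dims %d, %d)\n",
              x$mean_cc, x$retained_dims[1], x$retained_dims[2]))
  invisible(x)
}

#' Pairwise SVCCA stability summary over a model registry
#'
#' @param registry a `bombe_registry` from [run_grid()].
#' @param scope `"within_algorithm"` (all seed pairs at fixed algorithm and
#'   k), `"across_algorithms"` (all cross-algorithm pairs at fixed k), or
#'   `"across_dimensions"` (all seed pairs between two dimensionalities
#'   within an algorithm).
#' @param data_tag which data context to compare (`"real"` or
#'   `"permuted"`).
#' @param ... passed to [svcca()].
#' @return long data.frame with columns `algorithm1`, `k1`, `seed1`,
#'   `algorithm2`, `k2`, `seed2`, `mean_cc`.
#' @export
stability_summary <- function(registry,
                              scope = c("within_algorithm",
                                        "across_algorithms",
                                        "across_dimensions"),
                              data_tag = "real", ...) {
  stopifnot(inherits(registry, "bombe_registry"))
  scope <- match.arg(scope)
  pairs <- list()
  add_pair <- function(m1, m2) {
    if (is.null(m1) || is.null(m2)) return()
    res <- svcca(m1$W, m2$W, ...)
    pairs[[length(pairs) + 1L]] <<- data.frame(
      algorithm1 = m1$algorithm, k1 = m1$k, seed1 = m1$seed,
      algorithm2 = m2$algorithm, k2 = m2$k, seed2 = m2$seed,
      mean_cc = res$mean_cc, stringsAsFactors = FALSE
    )
  }
  get <- function(alg, k, seed) {
    registry$models[[model_key(alg, k, seed, data_tag)]]
  }
  seeds <- registry$seeds
  if (scope == "within_algorithm") {
    for (alg in registry$algorithms) for (k in registry$k_grid) {
      for (i in seq_along(seeds)) for (j in seq_along(seeds)) {
        if (i < j) add_pair(get(alg, k, seeds[i]), get(alg, k, seeds[j]))
      }
    }
  } else if (scope == "across_algorithms") {
    algs <- registry$algorithms
    for (k in registry$k_grid) {
      for (a in seq_along(algs)) for (b in seq_along(algs)) {
        if (a >= b) next
        for (s1 in seeds) for (s2 in seeds) {
          add_pair(get(algs[a], k, s1), get(algs[b], k, s2))
        }
      }
    }
  } else {
    kg <- registry$k_grid
    for (alg in registry$algorithms) {
      for (a in seq_along(kg)) for (b in seq_along(kg)) {
        if (a >= b) next
        for (s1 in seeds) for (s2 in seeds) {
          add_pair(get(alg, kg[a], s1), get(alg, kg[b], s2))
        }
      }
    }
  }
  do.call(rbind, c(pairs, make.row.names = FALSE))
}
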