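# Bipartite gene / gene-set membership networks: GMT parsing, membership
# (adjacency) matrices, and degree-preserving XSwap permutation.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene IDs.
#' @param name collection name.
#' @param universe gene IDs considered; members outside the universe are
#'   dropped and sets left empty after filtering are removed with a
#'   warning.  `NULL` keeps all members.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "collection", universe = NULL) {
  stop_if(is.null(names(sets)) || anyDuplicated(names(sets)),
          "set names must be present and unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (!is.null(universe)) {
    universe <- as.character(universe)
    sets <- lapply(sets, function(g) g[g %in% universe])
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warning("dropping ", sum(empty), " set(s) empty after universe filtering: ",
              toString(utils::head(names(sets)[empty], 5)))
      sets <- sets[!empty]
    }
  }
  structure(list(name = name, sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, %d member genes\n",
              x$name, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated with one set per line: name, description, then
#' member gene IDs.  Duplicate members within a set are collapsed; members
#' outside `universe` (when given) are dropped.
#'
#' @param path GMT file path.
#' @param universe optional gene universe filter.
#' @param name collection name (defaults to the file name).
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path, universe = NULL, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  stop_if(length(bad) > 0,
          "malformed GMT line(s) with fewer than 3 fields: line ",
          toString(utils::head(bad, 5)))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets, name = name, universe = universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the binary gene-set membership matrix H
#'
#' `H[s, g] = 1` iff gene `g` belongs to set `s`.  Columns follow
#' `gene_order` exactly, matching the row order of the weight matrices the
#' network is projected onto.
#'
#' @param collection a [gene_set_collection].
#' @param gene_order character vector of gene IDs fixing the column order.
#' @return gene-sets x genes binary matrix.
#' @export
build_membership <- function(collection, gene_order) {
  stopifnot(inherits(collection, "gene_set_collection"))
  stop_if(length(collection$sets) == 0L, "empty gene-set collection")
  gene_order <- as.character(gene_order)
  H <- matrix(0, nrow = length(collection$sets), ncol = length(gene_order),
              dimnames = list(names(collection$sets), gene_order))
  for (nm in names(collection$sets)) {
    H[nm, gene_order %in% collection$sets[[nm]]] <- 1
  }
  H
}

#' Degree-preserving XSwap permutation of a bipartite membership network
#'
#' Repeats `multiplier * edge_count` swap attempts.  Each attempt draws two
#' distinct edges (s1, g1), (s2, g2) (sampling with replacement per
#' attempt; failed attempts count toward the budget); if the four endpoints
#' are distinct on both sides and neither (s1, g2) nor (s2, g1) already
#' exists, the two edges are rewired to (s1, g2), (s2, g1).  Every node's
#' degree -- each gene's number of gene-set memberships and each set's size
#' -- is preserved exactly, so the permuted networks control for biases
#' induced by uneven gene degree.
#'
#' @param H binary gene-sets x genes matrix.
#' @param multiplier swap attempts per edge.
#' @param seed integer seed; deterministic given the seed.
#' @return permuted binary matrix with identical row and column sums.
#' @export
xswap <- function(H, multiplier = 10, seed = 0) {
  stop_if(!is.matrix(H) || !all(H %in% c(0, 1)), "H must be a binary matrix")
  edges <- which(H == 1, arr.ind = TRUE)
  n_edges <- nrow(edges)
  if (n_edges < 2L) return(H)
  out <- H
  s <- edges[, 1]
  g <- edges[, 2]
  with_seed(seed, {
    n_attempts <- ceiling(multiplier * n_edges)
    picks <- matrix(sample.int(n_edges, 2 * n_attempts, replace = TRUE),
                    ncol = 2)
    for (a in seq_len(n_attempts)) {
      i <- picks[a, 1]; j <- picks[a, 2]
      if (i == j) next
      s1 <- s[i]; g1 <- g[i]; s2 <- s[j]; g2 <- g[j]
      if (s1 == s2 || g1 == g2) next
      if (out[s1, g2] == 1 || out[s2, g1] == 1) next
      out[s1, g1] <- 0; out[s2, g2] <- 0
      out[s1, g2] <- 1; out[s2, g1] <- 1
      g[i] <- g2; g[j] <- g1
    }
  })
  out
}

#' Ensemble of independently XSwap-permuted membership networks
#'
#' @param H binary gene-sets x genes matrix.
#' @param n_permutations number of permuted networks (default 10).
#' @param base_seed base seed; permutation `i` uses a seed derived from it.
#' @param multiplier swap attempts per edge, passed to [xswap()].
#' @return object of class `permuted_ensemble`: list with `$permutations`
#'   (list of matrices), `$seeds`, `$multiplier`.
#' @export
permuted_ensemble <- function(H, n_permutations = 10, base_seed = 0,
                              multiplier = 10) {
  stop_if(!is_count(n_permutations), "n_permutations must be >= 1")
  seeds <- vapply(seq_len(n_permutations),
                  function(i) derive_seed(base_seed, i), integer(1))
  perms <- lapply(seeds, function(s) xswap(H, multiplier = multiplier, seed = s))
  structure(list(permutations = perms, seeds = seeds, multiplier = multiplier),
            class = "permuted_ensemble")
}

#' @export
print.permuted_ensemble <- function(x, ...) {
  cat(sprintf("permuted_ensemble: %d degree-preserving permutations (multiplier %g)\n",
              length(x$permutations), x$multiplier))
  invisible(x)
}
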