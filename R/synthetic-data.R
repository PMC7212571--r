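# Synthetic expression data with planted latent factors.
#
# The generator emulates the structure of processed bulk RNA-seq compendia:
# non-negative expression values, blocks of co-regulated genes driven by
# latent factors that coincide with known gene sets, tissue-group structure,
# and binary sample traits.  It exists so that the full compression +
# network-projection pipeline can be validated end-to-end on data whose
# ground truth is known.

#' Specification of a synthetic expression dataset
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_factors number of planted latent factors.
#' @param genes_per_factor number of genes loading on each factor; factors
#'   load on disjoint gene blocks, so `n_factors * genes_per_factor` must
#'   not exceed `n_genes`.
#' @param factor_strength magnitude of the non-zero loadings.
#' @param noise_sd standard deviation of the i.i.d. Gaussian measurement
#'   noise added on top of the factor model.
#' @param n_tissues number of tissue groups; each tissue has its own mean
#'   factor-activity profile.
#' @param trait_effects named numeric vector mapping factor index (as a
#'   character, e.g. `"1"`) to the shift in that factor's activity between
#'   the two trait groups.
#' @param n_decoy_sets number of decoy gene sets written alongside the
#'   planted ones.
#' @param decoy_set_size number of genes per decoy set.
#' @param seed integer seed making the dataset reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 500, n_genes = 2000, n_factors = 3,
                           genes_per_factor = 50, factor_strength = 1,
                           noise_sd = 0.1, n_tissues = 4,
                           trait_effects = c("1" = 1),
                           n_decoy_sets = 20, decoy_set_size = 50,
                           seed = 42) {
  spec <- list(
    n_samples = n_samples, n_genes = n_genes, n_factors = n_factors,
    genes_per_factor = genes_per_factor, factor_strength = factor_strength,
    noise_sd = noise_sd, n_tissues = n_tissues,
    trait_effects = trait_effects, n_decoy_sets = n_decoy_sets,
    decoy_set_size = decoy_set_size, seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  counts <- c("n_samples", "n_genes", "n_factors", "genes_per_factor",
              "n_tissues", "n_decoy_sets", "decoy_set_size")
  for (field in counts) {
    stop_if(!is_count(spec[[field]]),
            "synthetic_spec: '", field, "' must be a count >= 1")
  }
  stop_if(!is.numeric(spec$noise_sd) || spec$noise_sd < 0,
          "synthetic_spec: 'noise_sd' must be >= 0")
  stop_if(spec$n_factors * spec$genes_per_factor > spec$n_genes,
          "synthetic_spec: n_factors * genes_per_factor exceeds n_genes ",
          "(factors load on disjoint gene blocks)")
  if (length(spec$trait_effects)) {
    idx <- suppressWarnings(as.integer(names(spec$trait_effects)))
    stop_if(anyNA(idx) || any(idx < 1) || any(idx > spec$n_factors),
            "synthetic_spec: trait_effects names must index factors 1..",
            spec$n_factors)
  }
  invisible(spec)
}

#' Generate a synthetic expression matrix with planted latent factors
#'
#' Samples factor activities Z (with tissue-specific means and trait-shifted
#' columns), disjoint-block gene loadings L, and returns
#' `X = Z L' + E` shifted by its global minimum so all values are
#' non-negative.  The shift (rather than clipping) preserves the correlation
#' structure; non-negativity is needed because NMF requires it and min-max
#' scaling follows in the pipeline anyway.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements:
#'   \describe{
#'     \item{expression}{samples x genes non-negative matrix, sample IDs as
#'       row names and gene IDs (Entrez-style strings) as column names.}
#'     \item{metadata}{data.frame with `sample_id`, `tissue`, `trait`.}
#'     \item{truth}{ground truth: `loading_matrix` (genes x factors),
#'       `factor_activity` (samples x factors), `planted_sets` (named list
#'       of gene-ID vectors, one per factor), `tissue_labels`,
#'       `trait_labels`.}
#'   }
#' @export
#' @examples
#' sim <- generate_expression(synthetic_spec(n_samples = 40, n_genes = 100,
#'                                           genes_per_factor = 10, seed = 1))
#' dim(sim$expression)
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_samples
    p <- spec$n_genes
    f <- spec$n_factors
    gene_ids <- as.character(seq_len(p) + 1000L)
    sample_ids <- sprintf("S%04d", seq_len(n))

    tissue_labels <- sample(rep_len(sprintf("tissue_%d", seq_len(spec$n_tissues)), n))
    trait_labels <- sample(rep_len(c(0L, 1L), n))

    # Factor activity: tissue-specific means, optional trait shift, unit noise.
    tissue_means <- matrix(stats::rnorm(spec$n_tissues * f, sd = 1),
                           nrow = spec$n_tissues, ncol = f)
    tissue_idx <- as.integer(factor(tissue_labels,
                                    levels = sprintf("tissue_%d", seq_len(spec$n_tissues))))
    Z <- tissue_means[tissue_idx, , drop = FALSE] +
      matrix(stats::rnorm(n * f), nrow = n, ncol = f)
    for (nm in names(spec$trait_effects)) {
      j <- as.integer(nm)
      Z[, j] <- Z[, j] + spec$trait_effects[[nm]] * trait_labels
    }

    # Disjoint-block loadings, magnitudes around factor_strength.
    L <- matrix(0, nrow = p, ncol = f)
    planted_sets <- vector("list", f)
    names(planted_sets) <- sprintf("planted_factor_%d", seq_len(f))
    for (j in seq_len(f)) {
      block <- ((j - 1L) * spec$genes_per_factor + 1L):(j * spec$genes_per_factor)
      L[block, j] <- spec$factor_strength *
        stats::runif(spec$genes_per_factor, 0.5, 1.5)
      planted_sets[[j]] <- gene_ids[block]
    }

    X <- Z %*% t(L)
    if (spec$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), nrow = n, ncol = p)
    }
    X <- X - min(X)
    dimnames(X) <- list(sample_ids, gene_ids)
    dimnames(Z) <- list(sample_ids, names(planted_sets))
    dimnames(L) <- list(gene_ids, names(planted_sets))

    list(
      expression = X,
      metadata = data.frame(sample_id = sample_ids, tissue = tissue_labels,
                            trait = trait_labels, stringsAsFactors = FALSE),
      truth = list(loading_matrix = L, factor_activity = Z,
                   planted_sets = planted_sets, tissue_labels = tissue_labels,
                   trait_labels = trait_labels)
    )
  })
}

#' Write planted and decoy gene sets to a GMT file
#'
#' One GMT record per planted set, followed by `n_decoy_sets` decoy records
#' whose genes are sampled uniformly from the expression gene universe
#' (without replacement within a set, with replacement across sets).
#'
#' @param truth the `truth` element returned by [generate_expression()].
#' @param path output GMT path.
#' @param universe character vector of candidate gene IDs (the expression
#'   matrix columns).
#' @param n_decoy_sets,decoy_set_size decoy configuration.
#' @param seed seed for decoy sampling.
#' @return the written [gene_set_collection] (invisibly).
#' @export
write_planted_gmt <- function(truth, path, universe,
                              n_decoy_sets = 20, decoy_set_size = 50,
                              seed = 42) {
  stop_if(decoy_set_size > length(universe),
          "decoy_set_size exceeds the size of the gene universe")
  sets <- truth$planted_sets
  with_seed(seed, {
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("decoy_%03d", i)]] <- sample(universe, decoy_set_size)
    }
  })
  collection <- gene_set_collection(sets, name = "planted_plus_decoys",
                                    universe = universe)
  write_gmt(collection, path)
  invisible(collection)
}
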