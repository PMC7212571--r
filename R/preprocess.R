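# Partitioning, scaling, permutation and gene filtering of expression
# matrices.  Expression matrices are plain numeric matrices with samples in
# rows (row names = sample IDs) and genes in columns (column names = gene
# IDs, handled as strings throughout).

check_expression <- function(x) {
  stop_if(!is.matrix(x) || !is.numeric(x), "expected a numeric matrix")
  stop_if(anyNA(x), "expression matrix contains missing values")
  stop_if(is.null(rownames(x)) || anyDuplicated(rownames(x)),
          "sample IDs (row names) must be present and unique")
  stop_if(is.null(colnames(x)) || anyDuplicated(colnames(x)),
          "gene IDs (column names) must be present and unique")
  invisible(x)
}

#' Stratified train/test split of an expression matrix
#'
#' Samples are split per stratum (e.g. tissue or cancer type) so that every
#' stratum is represented in roughly the requested proportion in each
#' partition.  Per stratum the training size is `round(fraction * size)`;
#' the remainder goes to test.  A stratum of size 1 is assigned to training
#' with a warning.
#'
#' @param x samples x genes expression matrix.
#' @param strata character/factor vector of stratum labels, one per sample
#'   (in row order of `x`, or named by sample ID).
#' @param train_fraction fraction of each stratum assigned to training.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train` and `test` (sub-matrices of `x`) and
#'   `train_ids`, `test_ids`.
#' @export
stratified_split <- function(x, strata, train_fraction = 0.9, seed = 0) {
  check_expression(x)
  stop_if(train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0, 1)")
  if (!is.null(names(strata))) strata <- strata[rownames(x)]
  stop_if(length(strata) != nrow(x) || anyNA(strata),
          "every sample needs a stratum label")
  strata <- as.character(strata)

  train_ids <- character(0)
  with_seed(seed, {
    for (s in sort(unique(strata))) {
      ids <- rownames(x)[strata == s]
      if (length(ids) == 1L) {
        warning("stratum '", s, "' has a single sample; assigned to train")
        train_ids <- c(train_ids, ids)
        next
      }
      n_train <- round(train_fraction * length(ids))
      n_train <- max(1L, min(length(ids) - 1L, n_train))
      train_ids <- c(train_ids, sample(ids, n_train))
    }
  })
  train_ids <- rownames(x)[rownames(x) %in% train_ids]
  test_ids <- setdiff(rownames(x), train_ids)
  list(train = x[train_ids, , drop = FALSE],
       test = x[test_ids, , drop = FALSE],
       train_ids = train_ids, test_ids = test_ids)
}

#' Scale every gene to the \[0, 1\] range
#'
#' Each gene column is mapped to \[0, 1\] by subtracting its minimum and
#' dividing by its range, using that column's own min/range.  Applied to a
#' partition in isolation: the pipeline splits first and scales second, so
#' train and test are each scaled with their own statistics.  Constant
#' (zero-range) genes map to all zeros rather than being dropped, keeping
#' the gene universe aligned across partitions.
#'
#' @param x samples x genes expression matrix.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
minmax_scale <- function(x) {
  check_expression(x)
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  scaled <- sweep(x, 2, mins, "-")
  nonconst <- ranges > 0
  scaled[, nonconst] <- sweep(scaled[, nonconst, drop = FALSE], 2,
                              ranges[nonconst], "/")
  scaled[, !nonconst] <- 0
  scaled
}

#' Permute expression values independently within each gene
#'
#' Shuffles every gene column independently across samples, destroying
#' gene-gene correlation structure while preserving each gene's marginal
#' distribution.  Models trained on such data provide the permuted baseline
#' against which real-data performance is compared.
#'
#' @param x samples x genes expression matrix.
#' @param seed integer seed; deterministic given the seed.
#' @return matrix of the same shape; each column is a permutation of the
#'   original column.
#' @export
permute_within_genes <- function(x, seed = 0) {
  check_expression(x)
  with_seed(seed, {
    out <- apply(x, 2, sample)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Keep the most variably expressed genes by median absolute deviation
#'
#' Ranks genes by raw median absolute deviation,
#' `MAD = median(|x - median(x)|)` (no consistency constant -- the ranking
#' is scale-invariant either way), and keeps the top `n`.  Ties are broken
#' deterministically by gene ID.
#'
#' @param x samples x genes expression matrix.
#' @param n number of genes to keep.
#' @return sub-matrix with the `n` selected genes, in their original
#'   column order.
#' @export
select_top_mad_genes <- function(x, n) {
  check_expression(x)
  stop_if(!is_count(n) || n > ncol(x),
          "n must be a count not exceeding the number of genes")
  mads <- apply(x, 2, function(col) stats::median(abs(col - stats::median(col))))
  keep <- colnames(x)[order(-mads, colnames(x))[seq_len(n)]]
  x[, colnames(x) %in% keep, drop = FALSE]
}

#' Read / write expression matrices as TSV
#'
#' Rows are samples, the first column (`sample_id`) holds sample IDs, and
#' remaining column names are gene IDs.
#'
#' @param path TSV path.
#' @return for the reader, a samples x genes numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  check_expression(m)
}

#' @rdname read_expression_tsv
#' @param x samples x genes matrix to write.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression(x)
  dt <- data.table::data.table(sample_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
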