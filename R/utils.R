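# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed; kept below .Machine$integer.max.
derive_seed <- function(base_seed, offset) {
  as.integer((as.numeric(base_seed) * 7919 + offset) %% 2147483647L)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

#' Area under the ROC curve via the rank (Mann-Whitney) statistic
#'
#' @param scores numeric predictions, larger meaning more positive.
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  stop_if(n_pos == 0L || n_neg == 0L, "auroc() needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the mean of the precision values at the rank of each
#' positive example, scanning predictions from most to least confident.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  stop_if(n_pos == 0L, "aupr() needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec_at_pos <- cumsum(y)[y == 1L] / which(y == 1L)
  mean(prec_at_pos)
}

#' Fraction of non-zero entries expressed as a percentage
#'
#' @param n_nonzero count of non-zero model coefficients (or a coefficient
#'   vector, in which case non-zeros are counted).
#' @param n_total total number of coefficients.
#' @param digits decimal places to round the percentage to.
#' @return percentage of non-zero coefficients.
#' @export
sparsity_percent <- function(n_nonzero, n_total, digits = 2) {
  if (length(n_nonzero) > 1L) n_nonzero <- sum(n_nonzero != 0)
  stop_if(n_total <= 0, "n_total must be positive")
  round(100 * n_nonzero / n_total, digits)
}
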