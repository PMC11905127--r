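#' Library-size and composition normalization factors
#'
#' Library size is the column sum. The composition factor is derived from a
#' trimmed mean of per-gene log2 expression ratios (M-values) against a
#' reference sample, trimming 30% from each tail of the M-values and 5%
#' from each tail of the average log expression (A-values), then rescaled
#' so the factors have geometric mean 1 across samples. The factor is
#' oriented so that a sample whose library is inflated by a few dominant
#' transcripts gets a factor above 1; the effective library size used for
#' CPM is lib_size / comp_factor (see [effective_lib_sizes()]). The
#' reference is the sample whose upper quartile of count proportions is
#' closest to the mean upper quartile.
#'
#' @param x A CountMatrix.
#' @return List with numeric vectors `lib_size` and `comp_factor` (named by
#'   sample) and the chosen `ref_sample`.
#' @export
normalization_factors <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  m <- x$counts
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("all-zero sample: ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  p <- sweep(m, 2, lib, "/")
  uq <- apply(p, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- 1 / vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(p[, j], p[, ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  list(lib_size = stats::setNames(lib, colnames(m)),
       comp_factor = stats::setNames(f, colnames(m)),
       ref_sample = colnames(m)[ref])
}

#' Effective library sizes
#'
#' Library size divided by the composition factor; the denominator of CPM.
#'
#' @param norm Output of [normalization_factors()].
#' @return Named numeric vector.
#' @export
effective_lib_sizes <- function(norm) {
  norm$lib_size / norm$comp_factor
}

# Trimmed mean of M-values for one sample against the reference, on count
# proportions. Genes with a zero in either sample are unusable for logs.
tmm_pair_factor <- function(p_obs, p_ref, trim_m = 0.3, trim_a = 0.05) {
  keep <- p_obs > 0 & p_ref > 0
  if (!any(keep)) return(1)
  M <- log2(p_obs[keep] / p_ref[keep])
  A <- 0.5 * log2(p_obs[keep] * p_ref[keep])
  if (max(abs(M)) < 1e-10) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(M, ties.method = "first") >= lo_m &
    rank(M, ties.method = "first") <= hi_m &
    rank(A, ties.method = "first") >= lo_a &
    rank(A, ties.method = "first") <= hi_a
  if (!any(keep2)) return(1)
  2^mean(M[keep2])
}
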