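#' Negative-binomial exact-style differential expression for one transition
#'
#' Tests each gene for a change in relative abundance between the two
#' consecutive spacetime points of a transition, within one FACS fraction.
#' Group counts are summed and the p-value is the conditional probability of
#' a split at least as extreme as the observed one given the total, under
#' equal proportions and the estimated dispersion; two-sided by doubling the
#' smaller tail, capped at 1. Fold changes use a prior count of 0.5 CPM so
#' they stay finite at zero counts. FDR is Benjamini-Hochberg within the
#' transition.
#'
#' Genes are filtered before testing: kept if CPM > `filter_min_cpm` in at
#' least `filter_min_samples` of the tested samples (all-zero genes always
#' dropped) — the filter affects the FDR denominator and is recorded by the
#' run manifest when used through the pipeline.
#'
#' @param x A CountMatrix.
#' @param transition "tau1", "tau2" or "tau3" (see [transition_levels()]).
#' @param fraction "GFP+" or "GFP-".
#' @param dispersion Optional named per-gene dispersion vector; estimated
#'   from the two tested groups when NULL.
#' @param norm Optional normalization factors for the full matrix.
#' @param filter_min_cpm,filter_min_samples Expression filter (defaults 1, 2).
#' @param prior_count Prior CPM added in fold changes (default 0.5).
#' @param prior_df Passed to [estimate_dispersion()] when estimating.
#' @return data.frame with gene, transition, log2fc, pvalue, fdr, mean_cpm.
#' @export
de_test <- function(x, transition, fraction = "GFP+", dispersion = NULL,
                    norm = NULL, filter_min_cpm = 1, filter_min_samples = 2,
                    prior_count = 0.5, prior_df = 10) {
  stopifnot(inherits(x, "CountMatrix"))
  tl <- transition_levels()
  if (!transition %in% names(tl)) {
    stop("unknown transition label: ", transition, call. = FALSE)
  }
  stages <- tl[[transition]]
  sel <- x$design$fraction == fraction & x$design$stage %in% stages
  if (!any(sel)) stop("no samples for ", transition, " in ", fraction, call. = FALSE)
  xs <- subset_counts(x, samples = x$design$sample_id[sel])
  grp <- factor(as.character(xs$design$stage), levels = stages)
  if (any(table(grp) < 2)) {
    stop("need >= 2 replicates in both conditions of ", transition, call. = FALSE)
  }
  norm_s <- normalization_factors(xs)
  eff <- effective_lib_sizes(norm_s)
  cpm_s <- sweep(xs$counts, 2, eff, "/") * 1e6

  keep <- rowSums(cpm_s > filter_min_cpm) >= filter_min_samples &
    rowSums(xs$counts) > 0
  if (!any(keep)) {
    return(data.frame(gene = character(), transition = character(),
                      log2fc = numeric(), pvalue = numeric(),
                      fdr = numeric(), mean_cpm = numeric()))
  }
  xs <- subset_counts(xs, genes = rownames(xs$counts)[keep])
  cpm_s <- cpm_s[keep, , drop = FALSE]

  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(xs, groups = grp, prior_df = prior_df,
                                      norm = norm_s)
  }
  phi <- dispersion[rownames(xs$counts)]
  phi[is.na(phi)] <- max(stats::median(dispersion, na.rm = TRUE), 1e-4)

  i1 <- grp == stages[1]
  i2 <- grp == stages[2]
  M1 <- sum(eff[i1]); M2 <- sum(eff[i2])
  S1 <- sum(eff[i1]^2); S2 <- sum(eff[i2]^2)
  t1 <- rowSums(xs$counts[, i1, drop = FALSE])
  t2 <- rowSums(xs$counts[, i2, drop = FALSE])

  pvals <- vapply(seq_len(nrow(xs$counts)), function(g) {
    nb_exact_pvalue(t1[g], t2[g], M1, M2, S1, S2, phi[g])
  }, numeric(1))

  m1 <- rowMeans(cpm_s[, i1, drop = FALSE])
  m2 <- rowMeans(cpm_s[, i2, drop = FALSE])
  log2fc <- log2((m2 + prior_count) / (m1 + prior_count))
  data.frame(
    gene = rownames(xs$counts),
    transition = transition,
    log2fc = log2fc,
    pvalue = pvals,
    fdr = stats::p.adjust(pvals, method = "BH"),
    mean_cpm = rowMeans(cpm_s),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Conditional NB exact p for one gene: group totals t1, t2; effective library
# masses M1, M2 (and their sums of squares S1, S2, which set the dispersion
# of each group total); per-sample dispersion phi. Two-sided by doubling the
# smaller tail, observed split included in both tails.
nb_exact_pvalue <- function(t1, t2, M1, M2, S1, S2, phi) {
  t <- t1 + t2
  if (t == 0) return(1)
  p_hat <- t / (M1 + M2)
  mu1 <- p_hat * M1
  mu2 <- p_hat * M2
  # var(T_k) = mu_k + phi_k mu_k^2 with phi_k = phi * S_k / M_k^2
  phi1 <- max(phi * S1 / M1^2, 1e-12)
  phi2 <- max(phi * S2 / M2^2, 1e-12)
  size1 <- 1 / phi1
  size2 <- 1 / phi2
  if (t <= 20000) {
    y <- 0:t
  } else {
    mhat <- t * mu1 / (mu1 + mu2)
    s <- sqrt(mhat * (1 + phi1 * mhat))
    lo <- max(0, floor(mhat - 50 * s))
    hi <- min(t, ceiling(mhat + 50 * s))
    lo <- min(lo, t1); hi <- max(hi, t1)
    y <- lo:hi
  }
  lp <- stats::dnbinom(y, size = size1, mu = mu1, log = TRUE) +
    stats::dnbinom(t - y, size = size2, mu = mu2, log = TRUE)
  mx <- max(lp)
  pr <- exp(lp - mx)
  pr <- pr / sum(pr)
  p_lo <- sum(pr[y <= t1])
  p_hi <- sum(pr[y >= t1])
  min(1, 2 * min(p_lo, p_hi))
}

#' Run differential expression over all three transitions
#'
#' Dispersion is estimated once per fraction, across all four stages (more
#' residual degrees of freedom than any single transition offers), and
#' shared by the three tests.
#'
#' @param x A CountMatrix.
#' @param fraction "GFP+" or "GFP-".
#' @param dispersion Optional per-gene dispersion; estimated across the
#'   fraction when NULL.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @param ... Passed to [de_test()].
#' @return Named list of DE tables, one per transition.
#' @export
de_all_transitions <- function(x, fraction = "GFP+", dispersion = NULL,
                               prior_df = 10, ...) {
  if (is.null(dispersion)) {
    sel <- x$design$fraction == fraction
    xf <- subset_counts(x, samples = x$design$sample_id[sel])
    dispersion <- estimate_dispersion(xf, groups = as.character(xf$design$stage),
                                      prior_df = prior_df)
  }
  lapply(stats::setNames(nm = names(transition_levels())), function(tr) {
    de_test(x, tr, fraction = fraction, dispersion = dispersion,
            prior_df = prior_df, ...)
  })
}

#' Significant genes of one transition
#'
#' Genes with FDR below `fdr_max` and absolute fold change above `min_fold`.
#'
#' @param results DE table from [de_test()] (one transition).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_fold Fold-change threshold on the natural scale (default 2).
#' @return Character vector of gene symbols.
#' @export
significant_genes <- function(results, fdr_max = 0.05, min_fold = 2) {
  if (!nrow(results)) return(character())
  results$gene[results$fdr < fdr_max & abs(results$log2fc) > log2(min_fold)]
}

#' Write a DE table as TSV
#' @param results DE table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_de <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
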