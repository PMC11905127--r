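#' Rank all genes by correlation with an anchor gene
#'
#' Computes the correlation of each detected gene with the anchor across all
#' samples (both fractions, all stages) on log2(CPM + 1) expression. The
#' p-value comes from the t transform t = r * sqrt((n - 2) / (1 - r^2)),
#' two-sided, with Benjamini-Hochberg adjustment. The anchor itself is
#' excluded from the output; ranks are 1..n by descending r.
#'
#' @param x A CountMatrix.
#' @param anchor Anchor gene symbol (e.g. "Gnrh1").
#' @param top_n Size of the signature attached as attribute "signature"
#'   (default 50).
#' @param method "pearson" (default) or "spearman".
#' @param norm Optional normalization factors.
#' @return data.frame with gene, r, pvalue, fdr, rank, ordered by rank, with
#'   attribute "signature" holding the top_n gene symbols.
#' @export
rank_by_anchor_correlation <- function(x, anchor, top_n = 50,
                                       method = c("pearson", "spearman"),
                                       norm = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  method <- match.arg(method)
  anchor <- toupper(anchor)
  e <- cpm(x, norm = norm, log = TRUE)
  if (ncol(e) < 3) stop("fewer than 3 samples", call. = FALSE)
  if (!anchor %in% rownames(e)) stop("anchor gene not found: ", anchor,
                                     call. = FALSE)
  a <- e[anchor, ]
  if (stats::sd(a) == 0) stop("anchor gene is constant across samples",
                              call. = FALSE)
  e <- e[setdiff(rownames(e), anchor), , drop = FALSE]
  e <- e[apply(e, 1, stats::sd) > 0, , drop = FALSE]  # constant genes have no r
  if (method == "spearman") {
    a <- rank(a)
    e <- t(apply(e, 1, rank))
  }
  n <- length(a)
  r <- as.vector(stats::cor(t(e), a))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  ord <- order(-r)
  out <- data.frame(gene = rownames(e)[ord], r = r[ord], pvalue = p[ord],
                    fdr = stats::p.adjust(p, "BH")[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- utils::head(out$gene, top_n)
  out
}

#' Expression-bin-matched gene-module score
#'
#' For a normalized expression matrix (samples or spots in rows, genes in
#' columns), genes are cut into `n_bins` equal-frequency bins by average
#' expression; for every set gene, `n_ctrl` control genes are sampled from
#' its bin (without replacement where the bin allows, otherwise the whole
#' bin), set genes being excluded from the control pools. The score of each
#' sample is the mean over set genes minus the mean over the pooled control
#' genes. Deterministic under a fixed seed.
#'
#' @param expr Numeric matrix, samples x genes (normalized expression).
#' @param gene_set Character vector of gene symbols, subset of colnames.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for control-gene sampling.
#' @return Named numeric vector of per-sample scores, with attribute
#'   "control_genes".
#' @export
module_score <- function(expr, gene_set, n_bins = 25, n_ctrl = 100, seed = 1L) {
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  gene_set <- unique(toupper(gene_set))
  colnames(expr) <- toupper(colnames(expr))
  missing <- setdiff(gene_set, colnames(expr))
  if (length(missing)) stop("set genes absent from matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  avg <- colMeans(expr)
  bins <- cut_equal_frequency(avg, n_bins)
  ctrl <- local_seed(seed, {
    unique(unlist(lapply(gene_set, function(g) {
      pool <- setdiff(names(avg)[bins == bins[g]], gene_set)
      if (!length(pool)) return(character())
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    })))
  })
  set_mean <- rowMeans(expr[, gene_set, drop = FALSE])
  ctrl_mean <- if (length(ctrl)) rowMeans(expr[, ctrl, drop = FALSE]) else 0
  score <- set_mean - ctrl_mean
  attr(score, "control_genes") <- ctrl
  score
}

# Equal-frequency binning on rank (ties broken by order), named by element.
cut_equal_frequency <- function(v, n_bins) {
  rk <- rank(v, ties.method = "first")
  b <- ceiling(rk / (length(v) / n_bins))
  b <- pmin(pmax(b, 1L), n_bins)
  names(b) <- names(v)
  b
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed for hierarchical stream splitting; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
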