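#' Over-representation of a gene list within trajectory gene sets
#'
#' Query and sets are first intersected with the background universe (by
#' default, the genes surviving the expression filter and tested for
#' trajectories). For each set, the p-value is the one-sided hypergeometric
#' upper tail P(X >= k) with k the overlap, drawing |query| genes from a
#' background containing |set| successes. Recall is k / |set|, the ratio
#' between intersection size and term size. Adjustment across sets is
#' Bonferroni by default (BH optional); results are ordered by adjusted p,
#' ties broken by recall.
#'
#' @param query Character vector of gene symbols.
#' @param sets A [gene_set_collection()].
#' @param background Character vector: the gene universe.
#' @param method Multiple-testing method, "bonferroni" (default) or "bh".
#' @return data.frame with set_name, intersection_size, term_size,
#'   query_size, background_size, recall, pvalue, adjusted_p.
#' @export
enrich_sets <- function(query, sets, background,
                        method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- intersect(unique(toupper(query)), background)
  if (!length(query)) {
    stop("query disjoint from background (identifier namespace mismatch?)",
         call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    m <- length(s)
    k <- length(intersect(query, s))
    p <- if (m == 0) 1 else hyper_upper_tail(k, m, N, n)
    data.frame(set_name = nm, intersection_size = k, term_size = m,
               query_size = n, background_size = N,
               recall = if (m > 0) k / m else 0,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_name = character(), intersection_size = integer(),
                      term_size = integer(), query_size = integer(),
                      background_size = integer(), recall = numeric(),
                      pvalue = numeric(), adjusted_p = numeric()))
  }
  out$adjusted_p <- stats::p.adjust(out$pvalue,
                                    method = if (method == "bh") "BH" else "bonferroni")
  out[order(out$adjusted_p, out$pvalue, -out$recall), , drop = FALSE]
}

#' One-sided hypergeometric upper tail P(X >= k)
#'
#' Probability of an overlap of at least `k` when `n` genes are drawn
#' without replacement from a background of `N` genes containing `m`
#' successes. Vectorized over all arguments.
#'
#' @param k Observed overlap.
#' @param m Term (set) size within the background.
#' @param N Background size.
#' @param n Query size within the background.
#' @return P(X >= k).
#' @export
hyper_upper_tail <- function(k, m, N, n) {
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Read a plain gene list (one symbol per line)
#' @param path Text file.
#' @return Character vector of uppercased symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  g <- trimws(readLines(path))
  unique(toupper(g[nzchar(g)]))
}
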