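#' All 27 trajectory codes
#'
#' A trajectory code is the triplet of up/flat/down calls over the three
#' consecutive transitions, written with characters {+, 0, -}, e.g. "+00".
#'
#' @return Character vector of the 27 code strings ("000" first).
#' @export
trajectory_codes <- function() {
  g <- expand.grid(d3 = c("0", "+", "-"), d2 = c("0", "+", "-"),
                   d1 = c("0", "+", "-"), stringsAsFactors = FALSE)
  paste0(g$d1, g$d2, g$d3)[order(paste0(g$d1, g$d2, g$d3) != "000")]
}

code_to_triplet <- function(code) {
  ch <- strsplit(code, "")[[1]]
  if (length(ch) != 3 || !all(ch %in% c("+", "0", "-"))) {
    stop("invalid trajectory code: ", code, call. = FALSE)
  }
  vapply(ch, function(c) switch(c, "+" = 1L, "0" = 0L, "-" = -1L), integer(1),
         USE.NAMES = FALSE)
}

triplet_to_code <- function(d) {
  paste(vapply(d, function(x) c("-", "0", "+")[x + 2L], character(1)),
        collapse = "")
}

negate_code <- function(code) {
  chartr("+-", "-+", code)
}

#' Encode per-gene spatiotemporal trajectories from the three transitions
#'
#' Per transition, a gene is called +1 if its raw p-value is below `p_max`
#' and its log2 fold change exceeds log2(`min_fold`), -1 if the p-value
#' passes and the fold change is below -log2(`min_fold`), else 0. Raw
#' p-values (not FDR) are used at this step. Genes tested in only some
#' transitions are assigned 0 at the missing ones, with a warning.
#'
#' @param de Named list of DE tables for "tau1", "tau2", "tau3" of one
#'   fraction (from [de_all_transitions()]).
#' @param p_max Raw p-value threshold (default 0.01).
#' @param min_fold Fold-change threshold, natural scale (default 2).
#' @param fraction Fraction label recorded in the output.
#' @return data.frame with columns gene, code, fraction (one row per tested
#'   gene).
#' @export
encode_trajectories <- function(de, p_max = 0.01, min_fold = 2,
                                fraction = "GFP+") {
  taus <- names(transition_levels())
  if (!all(taus %in% names(de))) {
    stop("need DE results for all of: ", paste(taus, collapse = ", "),
         call. = FALSE)
  }
  lfc_min <- log2(min_fold)
  genes <- sort(unique(unlist(lapply(de[taus], `[[`, "gene"))))
  calls <- matrix(0L, nrow = length(genes), ncol = 3,
                  dimnames = list(genes, taus))
  partial <- FALSE
  for (k in seq_along(taus)) {
    d <- de[[taus[k]]]
    idx <- match(d$gene, genes)
    up <- d$pvalue < p_max & d$log2fc > lfc_min
    dn <- d$pvalue < p_max & d$log2fc < -lfc_min
    calls[idx[up], k] <- 1L
    calls[idx[dn], k] <- -1L
    if (length(idx) < length(genes)) partial <- TRUE
  }
  if (partial) {
    warning("some genes were not tested in every transition; ",
            "missing transitions coded 0", call. = FALSE)
  }
  codes <- apply(calls, 1, triplet_to_code)
  data.frame(gene = genes, code = unname(codes), fraction = fraction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Materialize trajectory gene sets from an assignment
#'
#' One gene set per non-flat code with at least `min_genes` members; the
#' flat code "000" is never a set. Sets are named by the canonical code
#' string unless an alias table maps codes to labels.
#'
#' @param assignment data.frame from [encode_trajectories()].
#' @param min_genes Minimum set size (default 10).
#' @param aliases Optional named character vector mapping code -> label
#'   (e.g. c("+00" = "T01")).
#' @return A [gene_set_collection()].
#' @export
build_trajectory_sets <- function(assignment, min_genes = 10, aliases = NULL) {
  if (!nrow(assignment)) stop("empty trajectory assignment", call. = FALSE)
  keep <- assignment$code != "000"
  sets <- split(assignment$gene[keep], assignment$code[keep])
  sets <- sets[lengths(sets) >= min_genes]
  if (!is.null(aliases)) {
    hit <- names(sets) %in% names(aliases)
    names(sets)[hit] <- aliases[names(sets)[hit]]
  }
  gene_set_collection(sets,
    stats::setNames(paste0("trajectory ", names(sets)), names(sets)))
}

#' Write a trajectory assignment as TSV
#' @param assignment data.frame from [encode_trajectories()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
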