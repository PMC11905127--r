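#' Developmental stage vocabulary
#'
#' The four (stage, region) sampling cells of the design, in developmental
#' order: nasal compartment at E12.5 and E14.5, then brain compartment at
#' E14.5 and E18.5.
#'
#' @return Character vector of the four stage labels, in order.
#' @export
stage_levels <- function() {
  c("E12.5-nose", "E14.5-nose", "E14.5-brain", "E18.5-brain")
}

#' Stage-transition vocabulary
#'
#' The three consecutive transitions between the four spacetime points.
#'
#' @return Named list mapping transition labels ("tau1", "tau2", "tau3") to
#'   character vectors c(from, to).
#' @export
transition_levels <- function() {
  s <- stage_levels()
  list(tau1 = c(s[1], s[2]), tau2 = c(s[2], s[3]), tau3 = c(s[3], s[4]))
}

#' FACS fraction vocabulary
#' @return Character vector c("GFP+", "GFP-").
#' @export
fraction_levels <- function() c("GFP+", "GFP-")

#' Construct a validated sample design table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param stage Character vector of stage labels (see [stage_levels()]).
#' @param fraction Character vector, "GFP+" or "GFP-".
#' @param replicate Positive integer vector of replicate indices.
#' @return A data.frame with columns sample_id, stage (ordered factor),
#'   fraction (factor) and replicate.
#' @export
sample_design <- function(sample_id, stage, fraction, replicate) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(stage)), stage_levels())
  if (length(bad)) {
    stop("unknown stage label: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  badf <- setdiff(unique(as.character(fraction)), fraction_levels())
  if (length(badf)) {
    stop("unknown fraction label: ", paste(badf, collapse = ", "), call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  data.frame(
    sample_id = sample_id,
    stage = factor(stage, levels = stage_levels(), ordered = TRUE),
    fraction = factor(fraction, levels = fraction_levels()),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
}

#' Construct a validated gene-by-sample count matrix
#'
#' Gene symbols are uppercased so mouse- and human-style capitalisation of
#' the same symbol collide rather than silently coexist.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Column
#'   names must match `design$sample_id`.
#' @param design Sample design table as returned by [sample_design()].
#' @return An object of class "CountMatrix": a list with elements `counts`
#'   (integer matrix, uppercased unique rownames) and `design`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("non-integer counts", call. = FALSE)
  }
  storage.mode(counts) <- "double"  # doubles hold exact integers; avoids overflow on sums
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene symbols after case normalization", call. = FALSE)
  }
  if (!is.data.frame(design) || !all(c("sample_id", "stage", "fraction", "replicate") %in% names(design))) {
    stop("design must have sample_id, stage, fraction, replicate", call. = FALSE)
  }
  missing_samples <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_samples)) {
    stop("samples absent from design: ", paste(missing_samples, collapse = ", "),
         call. = FALSE)
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  design <- sample_design(design$sample_id, as.character(design$stage),
                          as.character(design$fraction), design$replicate)
  structure(list(counts = counts, design = design), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(stage = x$design$stage, fraction = x$design$fraction))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or samples
#'
#' @param x A CountMatrix.
#' @param genes Optional character vector of gene symbols to keep.
#' @param samples Optional character vector or logical mask of samples.
#' @return A CountMatrix.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[toupper(genes), , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  design <- x$design[match(colnames(m), x$design$sample_id), , drop = FALSE]
  count_matrix(m, design)
}

#' Counts per million
#'
#' CPM on effective library sizes (column sum divided by the composition
#' factor).
#'
#' @param x A CountMatrix.
#' @param norm Optional normalization factors from [normalization_factors()];
#'   computed if NULL. Use `norm = FALSE` for plain library-size CPM.
#' @param log If TRUE return log2(CPM + 1).
#' @return Numeric matrix, genes x samples.
#' @export
cpm <- function(x, norm = NULL, log = FALSE) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(norm)) norm <- normalization_factors(x)
  if (isFALSE(norm)) {
    eff <- colSums(x$counts)
  } else {
    eff <- effective_lib_sizes(norm)
    if (!all(colnames(x$counts) %in% names(eff))) {
      stop("normalization factors do not cover all samples", call. = FALSE)
    }
    eff <- eff[colnames(x$counts)]
  }
  out <- sweep(x$counts, 2, eff, "/") * 1e6
  if (log) out <- log2(out + 1)
  out
}
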