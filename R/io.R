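#' Read a sample design table
#'
#' @param path TSV with columns sample_id, stage, fraction, replicate.
#' @return Validated design data.frame (see [sample_design()]).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "stage", "fraction", "replicate")
  if (!all(need %in% names(d))) {
    stop("design file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sample_design(d$sample_id, d$stage, d$fraction, d$replicate)
}

#' Read a gene-by-sample count matrix
#'
#' Accepts a dense TSV (gene symbols in the first column, one column per
#' sample) or a MatrixMarket triplet file (`*.mtx`) with plain-text row and
#' column sidecar files (one gene / one sample id per line).
#'
#' @param path Count file (TSV or .mtx).
#' @param design_path TSV design file (see [read_design()]).
#' @param rows_path,cols_path Sidecar paths for MTX input; default
#'   `<path>.rows` and `<path>.cols`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design_path, rows_path = NULL, cols_path = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  design <- read_design(design_path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(rows_path)) rows_path <- paste0(path, ".rows")
    if (is.null(cols_path)) cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path)) {
      stop("missing MTX sidecar files: ", rows_path, ", ", cols_path, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rows_path)
    colnames(m) <- readLines(cols_path)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    genes <- as.character(d[[1]])
    m <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-integer counts", call. = FALSE)
    rownames(m) <- genes
  }
  count_matrix(m, design)
}

#' Write a CountMatrix (and its design) to disk
#'
#' @param x A CountMatrix.
#' @param path Output count file; `*.mtx` selects MatrixMarket triplet with
#'   `.rows`/`.cols` sidecars, anything else a dense TSV.
#' @param design_path Output design TSV.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(x, path, design_path) {
  stopifnot(inherits(x, "CountMatrix"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(rownames(x$counts), paste0(path, ".rows"))
    writeLines(colnames(x$counts), paste0(path, ".cols"))
  } else {
    d <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  d <- x$design
  d$stage <- as.character(d$stage)
  d$fraction <- as.character(d$fraction)
  utils::write.table(d, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are deduplicated; duplicate set names and
#' lines with fewer than three fields are errors.
#'
#' @param path GMT file.
#' @return A named list of character vectors (class "GeneSetCollection",
#'   with a "description" attribute per set).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gene-set file: ", path, call. = FALSE)
    return(gene_set_collection(list()))
  }
  sets <- list()
  desc <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 40), call. = FALSE)
    }
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm, call. = FALSE)
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set: ", nm, call. = FALSE)
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param description Optional named character vector of descriptions.
#' @return List of uppercased gene symbol vectors, class "GeneSetCollection".
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop("set names must be present and unique", call. = FALSE)
    }
    if (any(!lengths(sets))) stop("empty gene set", call. = FALSE)
    sets <- lapply(sets, function(g) unique(toupper(g)))
  }
  structure(sets, class = "GeneSetCollection",
            description = description %||%
              stats::setNames(rep("", length(sets)), names(sets)))
}

#' Write gene sets in GMT format
#'
#' @param sets A GeneSetCollection (or plain named list of gene vectors).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    if (!nzchar(d)) d <- "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

variant_consequences <- function() {
  c("stop_gain", "frameshift", "splice_site", "spliceai_predicted",
    "synonymous", "other")
}

variant_columns <- function() {
  c("variant_id", "gene", "cohort", "subject_id", "consequence",
    "popmax_af", "qual", "mq", "mq_rank_sum", "ad_ratio", "in_segdup",
    "local_db_count", "pedigree_count", "flagged_control_db", "indel_len",
    "allele_count", "spliceai_score")
}

#' Validate (and type) a variant table
#'
#' @param v Data frame with the variant-table columns; missing optional QC
#'   columns are added filled with NA (never with passing values).
#' @return Validated data.frame of class c("VariantTable", "data.frame").
#' @export
variant_table <- function(v) {
  need <- c("variant_id", "gene", "cohort", "consequence")
  if (!all(need %in% names(v))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(variant_columns(), names(v))) v[[col]] <- NA
  bad <- setdiff(unique(v$cohort), c("case", "control"))
  if (length(bad)) stop("cohort outside {case, control}: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  badc <- setdiff(unique(v$consequence), variant_consequences())
  if (length(badc)) stop("unknown consequence: ", paste(badc, collapse = ", "),
                         call. = FALSE)
  v$gene <- toupper(as.character(v$gene))
  num <- c("popmax_af", "qual", "mq", "mq_rank_sum", "ad_ratio",
           "spliceai_score")
  for (col in num) v[[col]] <- as.numeric(v[[col]])
  int <- c("local_db_count", "pedigree_count", "indel_len", "allele_count")
  for (col in int) v[[col]] <- as.integer(v[[col]])
  for (col in c("in_segdup", "flagged_control_db")) {
    v[[col]] <- as.logical(v[[col]])
  }
  ok <- is.na(v$ad_ratio) | (v$ad_ratio >= 0 & v$ad_ratio <= 1)
  if (!all(ok)) stop("ad_ratio outside [0,1]", call. = FALSE)
  ok <- is.na(v$popmax_af) | (v$popmax_af >= 0 & v$popmax_af <= 1)
  if (!all(ok)) stop("popmax_af outside [0,1]", call. = FALSE)
  if (any(!is.na(v$allele_count) & v$allele_count < 0)) {
    stop("negative allele_count", call. = FALSE)
  }
  if (any(!is.na(v$indel_len) & v$indel_len < 0)) {
    stop("negative indel_len", call. = FALSE)
  }
  v <- v[, variant_columns()]
  class(v) <- c("VariantTable", "data.frame")
  v
}

#' Read an annotated variant table
#'
#' Case rows carry subject identifiers; control rows are summary-level
#' (no subject_id, allele counts instead), matching public-database exports.
#'
#' @param path TSV with the variant-table columns.
#' @param cohort_sizes Optional named vector/list with elements `case` and
#'   `control` giving cohort sizes; attached as an attribute when supplied.
#' @return A validated VariantTable.
#' @export
read_variants <- function(path, cohort_sizes = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  v <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  v <- variant_table(v)
  if (!is.null(cohort_sizes)) {
    cohort_sizes <- as.list(cohort_sizes)
    if (any(unlist(cohort_sizes) <= 0)) stop("cohort sizes must be positive",
                                             call. = FALSE)
    attr(v, "cohort_sizes") <- cohort_sizes
  }
  v
}

#' Write a variant table as TSV
#' @param v A VariantTable.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(v, path) {
  utils::write.table(as.data.frame(v), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat YAML configuration file
#'
#' @param path YAML file of flat key: value pairs.
#' @param defaults Named list of default values; config values override
#'   defaults, and keys absent from `defaults` are kept as-is.
#' @return Named list.
#' @export
read_config <- function(path, defaults = list()) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  utils::modifyList(defaults, cfg)
}

#' Timestamped log line to stderr
#' @param fmt sprintf format string.
#' @param ... Values for `fmt`.
#' @return Invisibly, the formatted message.
#' @export
log_msg <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), msg)
  invisible(msg)
}

#' Write a machine-readable run manifest
#'
#' Records parameters, the seed and md5 hashes of the input files beside the
#' outputs, so a run can be audited and reproduced.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters.
#' @param seed Integer seed used for the run (or NULL).
#' @param inputs Character vector of input file paths to hash.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, params = list(), seed = NULL, inputs = character()) {
  hashes <- if (length(inputs)) {
    stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  } else NULL
  obj <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, params = params, input_md5 = as.list(hashes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
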