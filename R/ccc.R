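#' Centered unit stage profiles for one fraction
#'
#' For every gene, the mean log2(CPM + 1) per stage (in stage order) is
#' centered and scaled to unit Euclidean norm. Constant raw profiles are
#' flagged degenerate and kept as zero vectors; any interaction strength
#' with a degenerate profile is 0 by definition.
#'
#' @param x A CountMatrix.
#' @param fraction "GFP+" or "GFP-".
#' @param norm Optional normalization factors.
#' @return List with `profiles` (genes x 4 matrix of unit profiles),
#'   `stage_means` (raw per-stage mean log2 CPM), `degenerate` (logical),
#'   `max_cpm` (max per-stage mean CPM, for the expression gate) and
#'   `fraction`.
#' @export
stage_profiles <- function(x, fraction = "GFP+", norm = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  sel <- x$design$fraction == fraction
  if (!any(sel)) stop("no samples in fraction ", fraction, call. = FALSE)
  xs <- subset_counts(x, samples = x$design$sample_id[sel])
  stages <- stage_levels()
  present <- stages %in% as.character(xs$design$stage)
  if (!all(present)) {
    stop("missing stage in fraction ", fraction, ": ",
         paste(stages[!present], collapse = ", "), call. = FALSE)
  }
  cp <- cpm(xs, norm = norm)
  lg <- log2(cp + 1)
  stage_of <- as.character(xs$design$stage)
  means <- vapply(stages, function(s) {
    rowMeans(lg[, stage_of == s, drop = FALSE])
  }, numeric(nrow(lg)))
  max_cpm <- vapply(stages, function(s) {
    rowMeans(cp[, stage_of == s, drop = FALSE])
  }, numeric(nrow(cp)))
  max_cpm <- apply(max_cpm, 1, max)
  cu <- center_unit(means)
  list(profiles = cu$unit, stage_means = means, degenerate = cu$degenerate,
       max_cpm = max_cpm, fraction = fraction)
}

# Center each row and scale to unit Euclidean norm; constant rows are
# degenerate zero vectors. Invariant under positive affine transforms of
# the raw row.
center_unit <- function(means) {
  means <- as.matrix(means)
  centered <- means - rowMeans(means)
  nrm <- sqrt(rowSums(centered^2))
  degenerate <- nrm < 1e-12
  unit <- centered
  unit[!degenerate, ] <- centered[!degenerate, , drop = FALSE] /
    nrm[!degenerate]
  unit[degenerate, ] <- 0
  list(unit = unit, degenerate = degenerate)
}

#' Build the dynamic ligand-receptor communication network
#'
#' Each curated ligand-receptor pair becomes a directed edge from the ligand
#' (expressed in the surrounding GFP- cells) to the receptor (expressed in
#' the GnRH-neuron GFP+ fraction). Edge strength is the scalar product of
#' the two centered unit stage profiles — a cosine, equal to the Pearson
#' correlation of the four stage means — and lies in [-1, 1]. Edges are
#' classed parallel (> tau), anti-parallel (< -tau) or neutral. Pairs whose
#' ligand or receptor never reaches `expression_floor` CPM in any stage of
#' its fraction are dropped (the "expressed" gate), as are pairs naming
#' unknown genes (with a warning).
#'
#' @param pairs data.frame with columns `ligand` and `receptor`.
#' @param ligand_profiles [stage_profiles()] of the GFP- fraction.
#' @param receptor_profiles [stage_profiles()] of the GFP+ fraction.
#' @param assignments Optional list with elements `ligand` and `receptor`,
#'   each an [encode_trajectories()] table, used to annotate codes.
#' @param tau Classification threshold on |strength| (default 0.5).
#' @param expression_floor Minimum per-stage mean CPM to count a gene as
#'   expressed (default 1).
#' @return data.frame with ligand, receptor, strength, class, ligand_code,
#'   receptor_code.
#' @export
build_dynamic_network <- function(pairs, ligand_profiles, receptor_profiles,
                                  assignments = NULL, tau = 0.5,
                                  expression_floor = 1) {
  stopifnot(all(c("ligand", "receptor") %in% names(pairs)))
  lig <- toupper(pairs$ligand)
  rec <- toupper(pairs$receptor)
  known <- lig %in% rownames(ligand_profiles$profiles) &
    rec %in% rownames(receptor_profiles$profiles)
  if (any(!known)) {
    warning(sum(!known), " pair(s) referencing unknown genes dropped",
            call. = FALSE)
  }
  lig <- lig[known]; rec <- rec[known]
  expressed <- ligand_profiles$max_cpm[lig] >= expression_floor &
    receptor_profiles$max_cpm[rec] >= expression_floor
  lig <- lig[expressed]; rec <- rec[expressed]
  if (!length(lig)) {
    return(data.frame(ligand = character(), receptor = character(),
                      strength = numeric(), class = character(),
                      ligand_code = character(), receptor_code = character()))
  }
  strength <- rowSums(ligand_profiles$profiles[lig, , drop = FALSE] *
                        receptor_profiles$profiles[rec, , drop = FALSE])
  strength[ligand_profiles$degenerate[lig] |
             receptor_profiles$degenerate[rec]] <- 0
  cls <- ifelse(strength > tau, "parallel",
                ifelse(strength < -tau, "anti-parallel", "neutral"))
  code_of <- function(assign, genes) {
    if (is.null(assign)) return(rep(NA_character_, length(genes)))
    assign$code[match(genes, toupper(assign$gene))]
  }
  data.frame(
    ligand = lig, receptor = rec, strength = unname(strength),
    class = unname(cls),
    ligand_code = code_of(assignments$ligand, lig),
    receptor_code = code_of(assignments$receptor, rec),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Detect network modules by thresholded local connectivity
#'
#' Keeps edges with |strength| >= `min_abs_strength` and returns the
#' connected components of the resulting bipartite ligand/receptor graph
#' that contain at least `min_edges` edges. The summary strength of a module
#' is the mean |strength| of its edges.
#'
#' @param edges data.frame from [build_dynamic_network()].
#' @param min_abs_strength Edge inclusion threshold (default 0.8).
#' @param min_edges Minimum edges per module (default 2).
#' @return List of modules, each a list with `id`, `ligands`, `receptors`,
#'   `edges` (data.frame) and `summary_strength`.
#' @export
detect_modules <- function(edges, min_abs_strength = 0.8, min_edges = 2) {
  keep <- abs(edges$strength) >= min_abs_strength
  e <- edges[keep, , drop = FALSE]
  if (!nrow(e)) return(list())
  # prefix node names: a symbol may act as both ligand and receptor
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("L:", e$ligand), to = paste0("R:", e$receptor)),
    directed = FALSE
  )
  comp <- igraph::components(g)
  mods <- list()
  for (k in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == k]
    sub <- e[paste0("L:", e$ligand) %in% nodes &
               paste0("R:", e$receptor) %in% nodes, , drop = FALSE]
    if (nrow(sub) < min_edges) next
    mods[[length(mods) + 1L]] <- list(
      id = sprintf("m%d", length(mods) + 1L),
      ligands = sort(unique(sub$ligand)),
      receptors = sort(unique(sub$receptor)),
      edges = sub,
      summary_strength = mean(abs(sub$strength))
    )
  }
  mods
}

#' Write network edges as TSV and GraphML
#'
#' @param edges data.frame from [build_dynamic_network()].
#' @param tsv_path Output edge-list TSV.
#' @param graphml_path Optional GraphML output with node-role and edge
#'   attributes.
#' @return Invisibly, `tsv_path`.
#' @export
write_network <- function(edges, tsv_path, graphml_path = NULL) {
  utils::write.table(edges, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path) && nrow(edges)) {
    nodes <- data.frame(
      name = c(paste0("L:", unique(edges$ligand)),
               paste0("R:", unique(edges$receptor))),
      role = c(rep("ligand", length(unique(edges$ligand))),
               rep("receptor", length(unique(edges$receptor)))),
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("L:", edges$ligand),
                 to = paste0("R:", edges$receptor),
                 strength = edges$strength, class = edges$class),
      directed = TRUE, vertices = nodes
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}
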