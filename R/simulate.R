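#' Simulation parameters for the synthetic study design
#'
#' Defaults emulate the study design: four spacetime points by two FACS
#' fractions, negative-binomial counts with variance mu + phi * mu^2,
#' log-normal baseline means on the natural-log scale, a planted fold of
#' 2.5 per changing transition, and log-normal library-size factors.
#'
#' @param n_genes Number of genes (default 2000).
#' @param replicates_per_condition Replicates per (stage, fraction) cell
#'   (default 4).
#' @param baseline_log_mean Natural-log mean of expected counts (default 5).
#' @param baseline_log_sd Natural-log SD of expected counts (default 1.5).
#' @param dispersion NB dispersion phi (default 0.1).
#' @param planted_fold Fold applied per changing transition (> 1, default
#'   2.5).
#' @param library_size_cv Coefficient of variation of library-size factors
#'   (default 0.2).
#' @param seed Integer seed (default 1).
#' @return Named list of parameters (class "SimulationParams").
#' @export
sim_params <- function(n_genes = 2000, replicates_per_condition = 4,
                       baseline_log_mean = 5, baseline_log_sd = 1.5,
                       dispersion = 0.1, planted_fold = 2.5,
                       library_size_cv = 0.2, seed = 1L) {
  if (planted_fold <= 1) stop("planted_fold must exceed 1", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 replicates_per_condition = as.integer(replicates_per_condition),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, planted_fold = planted_fold,
                 library_size_cv = library_size_cv, seed = as.integer(seed)),
            class = "SimulationParams")
}

sim_design <- function(reps) {
  grid <- expand.grid(replicate = seq_len(reps), fraction = fraction_levels(),
                      stage = stage_levels(), stringsAsFactors = FALSE)
  id <- sprintf("%s_%s_r%d", gsub("[^A-Za-z0-9.]", "", grid$stage),
                ifelse(grid$fraction == "GFP+", "pos", "neg"), grid$replicate)
  sample_design(id, grid$stage, grid$fraction, grid$replicate)
}

# Per-stage expected counts implied by a trajectory code: stage i+1 mean is
# stage i mean times fold^(code element).
code_stage_means <- function(base_mean, code, fold) {
  d <- code_to_triplet(code)
  base_mean * fold^cumsum(c(0, d))
}

#' Simulate the stagewise count matrix with planted trajectories
#'
#' GFP+ genes follow their planted trajectory codes (stage mean multiplied
#' by planted_fold^d per transition); genes outside `trajectory_mix` are
#' flat ("000"). The GFP- fraction gets independent flat means unless a
#' ligand program is planted later by [simulate_lr_pairs()]. Counts are
#' NB(mean = s_j * mu_gi, dispersion phi) with log-normal library factors
#' s_j. Identical parameters and seed give byte-identical output.
#'
#' @param params A [sim_params()].
#' @param trajectory_mix Named integer vector code -> number of genes (may
#'   be empty for an all-flat null).
#' @return List with `counts` (a CountMatrix) and `truth` (data.frame gene,
#'   code).
#' @export
simulate_counts <- function(params = sim_params(), trajectory_mix = integer()) {
  mix <- trajectory_mix
  if (length(mix)) {
    bad <- setdiff(names(mix), trajectory_codes())
    if (length(bad)) stop("invalid trajectory code in mix: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (sum(mix) > params$n_genes) stop("trajectory_mix exceeds n_genes",
                                        call. = FALSE)
  }
  local_seed(derive_seed(params$seed, 1L), {
    n <- params$n_genes
    genes <- sprintf("G%05d", seq_len(n))
    codes <- rep("000", n)
    if (length(mix)) codes[seq_len(sum(mix))] <- rep(names(mix), mix)
    design <- sim_design(params$replicates_per_condition)
    base_pos <- exp(stats::rnorm(n, params$baseline_log_mean,
                                 params$baseline_log_sd))
    base_neg <- exp(stats::rnorm(n, params$baseline_log_mean,
                                 params$baseline_log_sd))
    sdlog <- sqrt(log(1 + params$library_size_cv^2))
    s <- exp(stats::rnorm(nrow(design), -sdlog^2 / 2, sdlog))
    mu_pos <- t(vapply(seq_len(n), function(g) {
      code_stage_means(base_pos[g], codes[g], params$planted_fold)
    }, numeric(4)))
    colnames(mu_pos) <- stage_levels()
    stage_idx <- match(as.character(design$stage), stage_levels())
    mu <- matrix(0, n, nrow(design))
    is_pos <- design$fraction == "GFP+"
    mu[, is_pos] <- mu_pos[, stage_idx[is_pos], drop = FALSE]
    mu[, !is_pos] <- matrix(base_neg, n, sum(!is_pos))
    mu <- sweep(mu, 2, s, "*")
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / params$dispersion),
                  nrow = n, dimnames = list(genes, design$sample_id))
    list(counts = count_matrix(cnt, design),
         truth = data.frame(gene = toupper(genes), code = codes,
                            stringsAsFactors = FALSE))
  })
}

#' Plant ligand-receptor co-dynamics into a simulated dataset
#'
#' Receptors are drawn from the planted (non-flat) GFP+ genes; ligand genes
#' are drawn from the flat remainder and their GFP- counts are overwritten
#' with a stage program: parallel pairs get the receptor's trajectory code
#' (same centered log profile), anti-parallel pairs the negated code
#' (reversed profile), and the remaining pairs an independent random code.
#'
#' @param sim Output of [simulate_counts()] (list with counts and truth).
#' @param params The [sim_params()] used for the simulation.
#' @param n_pairs Number of ligand-receptor pairs.
#' @param parallel_frac,anti_frac Fractions of pairs planted parallel and
#'   anti-parallel (defaults 1/3 each; the rest are independent).
#' @return List with `pairs` (data.frame ligand, receptor), `counts` (the
#'   amended CountMatrix) and `truth` (data.frame ligand, receptor,
#'   planted_class, ligand_code, receptor_code).
#' @export
simulate_lr_pairs <- function(sim, params, n_pairs, parallel_frac = 1 / 3,
                              anti_frac = 1 / 3) {
  truth <- sim$truth
  planted <- truth$gene[truth$code != "000"]
  if (n_pairs > length(planted)) {
    stop("n_pairs exceeds available planted receptor genes", call. = FALSE)
  }
  flat <- truth$gene[truth$code == "000"]
  if (n_pairs > length(flat)) stop("n_pairs exceeds available ligand genes",
                                   call. = FALSE)
  local_seed(derive_seed(params$seed, 2L), {
    receptors <- sample(planted, n_pairs)
    ligands <- sample(flat, n_pairs)
    n_par <- round(parallel_frac * n_pairs)
    n_anti <- round(anti_frac * n_pairs)
    cls <- c(rep("parallel", n_par), rep("anti-parallel", n_anti),
             rep("independent", n_pairs - n_par - n_anti))
    rec_code <- truth$code[match(receptors, truth$gene)]
    lig_code <- character(n_pairs)
    lig_code[cls == "parallel"] <- rec_code[cls == "parallel"]
    lig_code[cls == "anti-parallel"] <-
      vapply(rec_code[cls == "anti-parallel"], negate_code, character(1))
    n_ind <- sum(cls == "independent")
    if (n_ind) lig_code[cls == "independent"] <-
      sample(trajectory_codes(), n_ind, replace = TRUE)

    x <- sim$counts
    design <- x$design
    is_neg <- design$fraction == "GFP-"
    stage_idx <- match(as.character(design$stage), stage_levels())
    sdlog <- sqrt(log(1 + params$library_size_cv^2))
    base <- exp(stats::rnorm(n_pairs, params$baseline_log_mean,
                             params$baseline_log_sd))
    for (i in seq_len(n_pairs)) {
      mu_st <- code_stage_means(base[i], lig_code[i], params$planted_fold)
      mu_i <- mu_st[stage_idx[is_neg]]
      x$counts[ligands[i], is_neg] <-
        stats::rnbinom(sum(is_neg), mu = mu_i, size = 1 / params$dispersion)
    }
    list(pairs = data.frame(ligand = ligands, receptor = receptors,
                            stringsAsFactors = FALSE),
         counts = x,
         truth = data.frame(ligand = ligands, receptor = receptors,
                            planted_class = cls, ligand_code = lig_code,
                            receptor_code = rec_code,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate case/control variant tables with planted burden odds ratios
#'
#' Per trajectory set: control carriers are Binomial(n_controls, base rate)
#' emitted as summary allele counts; case carriers are Binomial(n_cases,
#' p_case) with p_case solving the planted odds ratio against the base
#' rate. Matched synonymous variants are generated with OR = 1 in both
#' cohorts. For every passing variant, `qc_fail_fraction` additional decoy
#' variants are emitted, each violating exactly one named QC filter,
#' cycling through the full filter vocabulary.
#'
#' @param trajectory_sets A [gene_set_collection()].
#' @param planted_or Named numeric vector set_name -> odds ratio (>= 1);
#'   sets not named get OR 1.
#' @param n_cases,n_controls Cohort sizes.
#' @param base_carrier_rate Control carrier probability per set (default
#'   0.01).
#' @param qc_fail_fraction Decoys emitted per passing variant (default 0.2).
#' @param planted_or_syn Named numeric vector set_name -> odds ratio for the
#'   synonymous class (default: OR 1 everywhere), for inflation-control
#'   scenarios.
#' @param seed Integer seed.
#' @return List with `variants` (VariantTable), `truth` (list with
#'   `odds_ratios` and `decoys` data.frames), `n_cases`, `n_controls`.
#' @export
simulate_variants <- function(trajectory_sets, planted_or = numeric(),
                              n_cases, n_controls, base_carrier_rate = 0.01,
                              qc_fail_fraction = 0.2,
                              planted_or_syn = numeric(), seed = 1L) {
  bad <- setdiff(c(names(planted_or), names(planted_or_syn)),
                 names(trajectory_sets))
  if (length(bad)) stop("planted_or names not in trajectory_sets: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  local_seed(derive_seed(seed, 3L), {
    rows <- list()
    decoys <- list()
    vid <- 0L
    p0 <- base_carrier_rate
    subjects <- sprintf("S%04d", seq_len(n_cases))
    ptv_cons <- c("stop_gain", "frameshift", "splice_site", "spliceai_predicted")
    passing_row <- function(gene, cohort, subject, consequence, ac) {
      vid <<- vid + 1L
      data.frame(
        variant_id = sprintf("v%06d", vid), gene = gene, cohort = cohort,
        subject_id = subject, consequence = consequence,
        popmax_af = sample(c(NA, 1e-5), 1), qual = 99, mq = 60,
        mq_rank_sum = 0, ad_ratio = 0.5, in_segdup = FALSE,
        local_db_count = 0L, pedigree_count = 0L,
        flagged_control_db = FALSE,
        indel_len = if (consequence == "frameshift") sample(1:3, 1) else 0L,
        allele_count = ac,
        spliceai_score = if (consequence == "spliceai_predicted") 0.9 else NA,
        stringsAsFactors = FALSE
      )
    }
    emit_cohort <- function(set_genes, cls, n_carriers, cohort) {
      if (n_carriers == 0) return()
      cons <- if (cls == "PTV") sample(ptv_cons, n_carriers, replace = TRUE)
        else rep("synonymous", n_carriers)
      genes <- sample(set_genes, n_carriers, replace = TRUE)
      if (cohort == "case") {
        subj <- sample(subjects, n_carriers)
        for (i in seq_len(n_carriers)) {
          rows[[length(rows) + 1L]] <<-
            passing_row(genes[i], "case", subj[i], cons[i], NA_integer_)
        }
      } else {
        # summary-level: group carriers into a handful of variants
        n_var <- max(1L, min(n_carriers, 6L))
        split <- as.vector(stats::rmultinom(1, n_carriers,
                                            rep(1 / n_var, n_var)))
        for (i in seq_len(n_var)) {
          if (split[i] == 0) next
          rows[[length(rows) + 1L]] <<-
            passing_row(genes[i], "control", NA_character_, cons[i], split[i])
        }
      }
    }
    case_rate <- function(or) {
      odds_case <- or * p0 / (1 - p0)
      p_case <- odds_case / (1 + odds_case)
      if (p_case >= 1) stop("requested odds ratio implies p_case >= 1",
                            call. = FALSE)
      p_case
    }
    for (nm in names(trajectory_sets)) {
      or <- if (nm %in% names(planted_or)) planted_or[[nm]] else 1
      or_s <- if (nm %in% names(planted_or_syn)) planted_or_syn[[nm]] else 1
      g <- trajectory_sets[[nm]]
      emit_cohort(g, "PTV", stats::rbinom(1, n_cases, case_rate(or)), "case")
      emit_cohort(g, "PTV", stats::rbinom(1, n_controls, p0), "control")
      emit_cohort(g, "synonymous",
                  stats::rbinom(1, n_cases, case_rate(or_s)), "case")
      emit_cohort(g, "synonymous", stats::rbinom(1, n_controls, p0), "control")
    }
    passing <- if (length(rows)) do.call(rbind, rows) else NULL
    n_pass <- length(rows)
    n_decoy <- round(qc_fail_fraction * n_pass)
    if (n_decoy > 0) {
      fails <- rep_len(filter_names(), n_decoy)
      templates <- passing[sample(n_pass, n_decoy, replace = TRUE), ,
                           drop = FALSE]
      for (i in seq_len(n_decoy)) {
        vid <- vid + 1L
        row <- templates[i, , drop = FALSE]
        row$variant_id <- sprintf("v%06d", vid)
        switch(fails[i],
               popmax = { row$popmax_af <- 2e-3 },
               qual = { row$qual <- 30 },
               mq = { row$mq <- 40 },
               mq_rank_sum = { row$mq_rank_sum <- -5 },
               ad_ratio = { row$ad_ratio <- 0.1 },
               segdup = { row$in_segdup <- TRUE },
               local_db = { row$local_db_count <- 10L },
               pedigree = { row$pedigree_count <- 10L },
               flagged = { row$flagged_control_db <- TRUE },
               indel_len = { row$indel_len <- 10L })
        rows[[length(rows) + 1L]] <- row
        decoys[[length(decoys) + 1L]] <-
          data.frame(variant_id = row$variant_id, fails = fails[i],
                     stringsAsFactors = FALSE)
      }
    }
    v <- if (length(rows)) variant_table(do.call(rbind, rows)) else
      variant_table(data.frame(variant_id = character(), gene = character(),
                               cohort = character(), consequence = character(),
                               stringsAsFactors = FALSE))
    list(variants = v,
         truth = list(
           odds_ratios = data.frame(
             set_name = names(trajectory_sets),
             planted_or = vapply(names(trajectory_sets), function(nm) {
               if (nm %in% names(planted_or)) planted_or[[nm]] else 1
             }, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL),
           decoys = if (length(decoys)) do.call(rbind, decoys) else
             data.frame(variant_id = character(), fails = character())),
         n_cases = n_cases, n_controls = n_controls)
  })
}

#' Simulate a trait-associated gene list with planted enrichment
#'
#' The list contains floor(overlap_fraction * list_size) genes from the
#' enriched trajectory set; the remainder is drawn uniformly from the
#' background minus all trajectory sets, so only the planted set is
#' enriched.
#'
#' @param trajectory_sets A [gene_set_collection()].
#' @param enriched_set Name of the set to enrich.
#' @param overlap_fraction Fraction of the list drawn from the enriched set.
#' @param list_size Size of the returned list.
#' @param background Character vector: gene universe.
#' @param seed Integer seed.
#' @return Character vector of gene symbols.
#' @export
simulate_trait_list <- function(trajectory_sets, enriched_set,
                                overlap_fraction, list_size, background,
                                seed = 1L) {
  background <- unique(toupper(background))
  if (length(background) < list_size) {
    stop("background smaller than list_size", call. = FALSE)
  }
  k <- floor(overlap_fraction * list_size)
  s <- trajectory_sets[[enriched_set]]
  if (is.null(s)) stop("unknown enriched_set: ", enriched_set, call. = FALSE)
  if (k > length(s)) {
    stop("overlap_fraction * list_size exceeds enriched set size",
         call. = FALSE)
  }
  pool <- setdiff(background, unique(unlist(trajectory_sets)))
  if (length(pool) < list_size - k) {
    stop("background (minus trajectory sets) too small", call. = FALSE)
  }
  local_seed(derive_seed(seed, 4L), {
    c(sample(s, k), sample(pool, list_size - k))
  })
}
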