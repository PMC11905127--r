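#' Variant QC filter configuration
#'
#' Defaults follow GATK-style hard filtering for a rare-disease cohort
#' against summary-level population controls: popmax allele frequency at
#' most 0.01% (1e-4), call quality >= 50, mapping quality >= 55, mapping
#' quality rank sum >= -2.5, allelic depth ratio >= 20%, no segmental
#' duplications, at most 3 hits in a local database of healthy individuals,
#' present in at most 5 pedigrees, not flagged in the control database,
#' indels of at most 3 nucleotides, and a splice-disruption score of at
#' least 0.5 for predicted splice variants to qualify as protein-truncating.
#'
#' @param ... Overrides for any threshold.
#' @return Named list of thresholds (class "FilterConfig").
#' @export
filter_config <- function(...) {
  cfg <- list(popmax_max = 1e-4, qual_min = 50, mq_min = 55, mqrs_min = -2.5,
              ad_ratio_min = 0.20, exclude_segdup = TRUE, local_db_max = 3L,
              pedigree_max = 5L, exclude_flagged = TRUE, indel_len_max = 3L,
              spliceai_min = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown filter setting: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "FilterConfig")
}

#' Names of the QC filters in the cascade
#' @return Character vector of the ten filter names.
#' @export
filter_names <- function() {
  c("popmax", "qual", "mq", "mq_rank_sum", "ad_ratio", "segdup",
    "local_db", "pedigree", "flagged", "indel_len")
}

# Logical matrix: row per variant, column per filter, TRUE = passes.
# Missing popmax passes (absent from the control database); any other
# missing QC value fails its filter rather than silently passing.
filter_pass_matrix <- function(v, cfg) {
  pass_num <- function(val, ok) !is.na(val) & ok
  cbind(
    popmax = is.na(v$popmax_af) | v$popmax_af <= cfg$popmax_max,
    qual = pass_num(v$qual, v$qual >= cfg$qual_min),
    mq = pass_num(v$mq, v$mq >= cfg$mq_min),
    mq_rank_sum = pass_num(v$mq_rank_sum, v$mq_rank_sum >= cfg$mqrs_min),
    ad_ratio = pass_num(v$ad_ratio, v$ad_ratio >= cfg$ad_ratio_min),
    segdup = if (cfg$exclude_segdup) !is.na(v$in_segdup) & !v$in_segdup else TRUE,
    local_db = pass_num(v$local_db_count, v$local_db_count <= cfg$local_db_max),
    pedigree = pass_num(v$pedigree_count, v$pedigree_count <= cfg$pedigree_max),
    flagged = if (cfg$exclude_flagged) {
      !is.na(v$flagged_control_db) & !v$flagged_control_db
    } else TRUE,
    indel_len = pass_num(v$indel_len, v$indel_len <= cfg$indel_len_max)
  )
}

#' Apply the QC filter cascade for one variant class
#'
#' Keeps variants of the requested class that pass every filter. The
#' protein-truncating (PTV) class is stop-gain, frameshift, splice-site, or
#' splice-disruption-predicted with score >= `spliceai_min`; the identical
#' cascade applies to synonymous variants, which serve as the inflation
#' control.
#'
#' @param v A VariantTable.
#' @param cfg A [filter_config()].
#' @param variant_class "PTV" or "synonymous".
#' @return The passing subset of `v`.
#' @export
filter_variants <- function(v, cfg = filter_config(),
                            variant_class = c("PTV", "synonymous")) {
  variant_class <- match.arg(variant_class)
  in_class <- if (variant_class == "PTV") {
    v$consequence %in% c("stop_gain", "frameshift", "splice_site") |
      (v$consequence == "spliceai_predicted" &
         !is.na(v$spliceai_score) & v$spliceai_score >= cfg$spliceai_min)
  } else {
    v$consequence == "synonymous"
  }
  pass <- rowSums(!filter_pass_matrix(v, cfg)) == 0
  out <- v[in_class & pass, , drop = FALSE]
  class(out) <- class(v)
  out
}

#' Carrier contingency table for one trajectory set
#'
#' Cases: distinct subjects with at least one passing variant in a gene of
#' the set (a subject with several qualifying variants counts once).
#' Controls are summary-level: every control variant is assumed to come
#' from a different individual, so control carriers are the sum of allele
#' counts over the set's passing variants, with a ceiling at the number of
#' controls.
#'
#' @param passing A filtered VariantTable (one variant class).
#' @param gene_set Character vector of gene symbols.
#' @param n_cases,n_controls Cohort sizes.
#' @return List (class "ContingencyTable") with a (case carriers), b (case
#'   non-carriers), c (control carriers), d (control non-carriers).
#' @export
build_contingency <- function(passing, gene_set, n_cases, n_controls) {
  gene_set <- toupper(gene_set)
  hit <- passing[passing$gene %in% gene_set, , drop = FALSE]
  cases <- hit[hit$cohort == "case", , drop = FALSE]
  a <- length(unique(cases$subject_id[!is.na(cases$subject_id)]))
  if (a > n_cases) stop("more case carriers than cases; inconsistent subject ids",
                        call. = FALSE)
  ctrl <- hit[hit$cohort == "control", , drop = FALSE]
  ac <- ctrl$allele_count
  ac[is.na(ac)] <- 1L
  cc <- min(sum(ac), n_controls)
  structure(list(a = a, b = n_cases - a, c = cc, d = n_controls - cc),
            class = "ContingencyTable")
}

#' One-sided Fisher test, odds ratio and Woolf confidence interval
#'
#' The p-value is the exact one-sided (enrichment in cases) hypergeometric
#' tail on the raw counts. The odds ratio is (a'd')/(b'c') and its 95% CI is
#' exp(log OR +/- 1.96 * sqrt(1/a' + 1/b' + 1/c' + 1/d')) (Woolf interval on
#' the log scale), where primes add the Haldane-Anscombe 0.5 to every cell
#' if and only if `haldane` and some cell is zero — the exact test always
#' uses the raw counts.
#'
#' @param t A [build_contingency()] table (or list with a, b, c, d).
#' @param haldane Apply the +0.5 correction when a cell is zero (default
#'   TRUE).
#' @param conf_level Confidence level (default 0.95).
#' @return List with or_hat, ci_low, ci_high, fisher_p, log_se.
#' @export
fisher_or_ci <- function(t, haldane = TRUE, conf_level = 0.95) {
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if (a + b == 0 || cc + d == 0) stop("empty cohort margin", call. = FALSE)
  # P(X >= a), X ~ Hypergeometric(carriers = a+c, total = a+b+c+d, drawn = a+b)
  fisher_p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  if (haldane && min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or_hat <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or_hat = or_hat, ci_low = exp(log(or_hat) - zq * se),
       ci_high = exp(log(or_hat) + zq * se), fisher_p = fisher_p,
       log_se = se)
}

#' z comparison between PTV and synonymous odds ratios
#'
#' z = (log OR_PTV - log OR_syn) / sqrt(SE_PTV^2 + SE_syn^2) with each SE
#' the Woolf log-scale standard error of its table; the p-value is the
#' one-sided upper normal tail (PTV odds ratio exceeding the synonymous
#' one).
#'
#' @param ptv,syn Lists from [fisher_or_ci()] (same trajectory set and
#'   cohort).
#' @return List with z and z_p.
#' @export
compare_or_z <- function(ptv, syn) {
  if (!is.finite(ptv$log_se) || !is.finite(syn$log_se)) {
    stop("degenerate standard error", call. = FALSE)
  }
  z <- (log(ptv$or_hat) - log(syn$or_hat)) / sqrt(ptv$log_se^2 + syn$log_se^2)
  list(z = z, z_p = stats::pnorm(z, lower.tail = FALSE))
}

#' Trajectory-collapsed rare-variant burden test
#'
#' For every trajectory gene set and every cohort stratum (all cases, plus
#' each subphenotype), applies the filter cascade to cases and controls,
#' builds PTV and synonymous carrier tables, runs the one-sided Fisher test
#' with Woolf CI, Bonferroni-corrects over the number of trajectory sets
#' within the stratum, and computes the PTV-vs-synonymous z. A set is
#' retained when its Bonferroni-corrected PTV enrichment passes `alpha` AND
#' the z test shows the PTV odds ratio significantly exceeding the
#' synonymous one.
#'
#' @param cases,controls VariantTables (controls summary-level).
#' @param trajectory_sets A [gene_set_collection()].
#' @param cfg A [filter_config()].
#' @param n_cases,n_controls Cohort sizes.
#' @param subphenotypes Optional named character vector subject_id ->
#'   subphenotype label (e.g. "KS"/"nCHH").
#' @param alpha Significance level for retention (default 0.05).
#' @return data.frame, one row per stratum x set x class, with columns
#'   stratum, set_name, class, a, b, c, d, or_hat, ci_low, ci_high,
#'   fisher_p, bonferroni_p, z, z_p, retained (z and retained reported on
#'   the PTV rows).
#' @export
run_burden <- function(cases, controls, trajectory_sets, cfg = filter_config(),
                       n_cases, n_controls, subphenotypes = NULL,
                       alpha = 0.05) {
  if (!length(trajectory_sets)) {
    return(data.frame(stratum = character(), set_name = character(),
                      class = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), or_hat = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      fisher_p = numeric(), bonferroni_p = numeric(),
                      z = numeric(), z_p = numeric(), retained = logical()))
  }
  strata <- list(all = NULL)
  if (!is.null(subphenotypes)) {
    for (lab in sort(unique(subphenotypes))) {
      strata[[lab]] <- names(subphenotypes)[subphenotypes == lab]
    }
  }
  n_sets <- length(trajectory_sets)
  out <- list()
  for (st in names(strata)) {
    case_v <- cases
    n_ca <- n_cases
    if (!is.null(strata[[st]])) {
      case_v <- cases[cases$subject_id %in% strata[[st]], , drop = FALSE]
      class(case_v) <- class(cases)
      n_ca <- length(strata[[st]])
    }
    pass <- list(
      PTV = list(case = filter_variants(case_v, cfg, "PTV"),
                 control = filter_variants(controls, cfg, "PTV")),
      synonymous = list(case = filter_variants(case_v, cfg, "synonymous"),
                        control = filter_variants(controls, cfg, "synonymous"))
    )
    for (nm in names(trajectory_sets)) {
      res <- lapply(pass, function(p) {
        both <- rbind(as.data.frame(p$case), as.data.frame(p$control))
        class(both) <- c("VariantTable", "data.frame")
        tab <- build_contingency(both, trajectory_sets[[nm]], n_ca, n_controls)
        c(list(table = tab), fisher_or_ci(tab))
      })
      zz <- compare_or_z(res$PTV, res$synonymous)
      bonf <- vapply(res, function(r) min(1, r$fisher_p * n_sets), numeric(1))
      retained <- bonf[["PTV"]] < alpha & zz$z_p < alpha
      for (cl in names(res)) {
        r <- res[[cl]]
        out[[length(out) + 1L]] <- data.frame(
          stratum = st, set_name = nm, class = cl,
          a = r$table$a, b = r$table$b, c = r$table$c, d = r$table$d,
          or_hat = r$or_hat, ci_low = r$ci_low, ci_high = r$ci_high,
          fisher_p = r$fisher_p, bonferroni_p = bonf[[cl]],
          z = if (cl == "PTV") zz$z else NA_real_,
          z_p = if (cl == "PTV") zz$z_p else NA_real_,
          retained = if (cl == "PTV") retained else NA,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Write a burden result table as TSV
#' @param results data.frame from [run_burden()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_burden <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
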