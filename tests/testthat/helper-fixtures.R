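# Shared in-code fixtures.

# Minimal balanced design: 4 stages x 2 fractions x `reps` replicates.
tiny_design <- function(reps = 1) {
  grid <- expand.grid(replicate = seq_len(reps),
                      fraction = fraction_levels(),
                      stage = stage_levels(), stringsAsFactors = FALSE)
  sample_design(sprintf("s%02d", seq_len(nrow(grid))),
                grid$stage, grid$fraction, grid$replicate)
}

# CountMatrix whose columns each sum to 1e6, so plain CPM equals the raw
# count. `profiles` is a named list gene -> numeric vector of counts per
# sample (length matching the design); a filler gene absorbs the remainder.
cpm_exact_matrix <- function(profiles, design) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  filler <- 1e6 - colSums(m)
  stopifnot(all(filler >= 0))
  m <- rbind(m, FILLER = filler)
  colnames(m) <- design$sample_id
  count_matrix(m, design)
}

# Deterministic variant fixture: one clean passing PTV per gene G1..G10 for
# case subjects S1..S10, plus one decoy per QC filter, each violating
# exactly that filter.
variant_fixture <- function() {
  base <- data.frame(
    variant_id = sprintf("p%02d", 1:10), gene = sprintf("G%d", 1:10),
    cohort = "case", subject_id = sprintf("S%d", 1:10),
    consequence = rep(c("stop_gain", "frameshift", "splice_site",
                        "spliceai_predicted", "stop_gain"), 2),
    popmax_af = NA, qual = 99, mq = 60, mq_rank_sum = 0, ad_ratio = 0.5,
    in_segdup = FALSE, local_db_count = 0L, pedigree_count = 0L,
    flagged_control_db = FALSE, indel_len = 0L, allele_count = NA,
    spliceai_score = NA, stringsAsFactors = FALSE
  )
  base$spliceai_score[base$consequence == "spliceai_predicted"] <- 0.9
  decoys <- base[rep(1, 10), ]
  decoys$variant_id <- sprintf("d%02d", 1:10)
  decoys$subject_id <- sprintf("S%d", 11:20)
  fail <- filter_names()
  decoys$popmax_af[fail == "popmax"][1] <- 2e-4
  decoys$qual[fail == "qual"] <- 30
  decoys$mq[fail == "mq"] <- 40
  decoys$mq_rank_sum[fail == "mq_rank_sum"] <- -5
  decoys$ad_ratio[fail == "ad_ratio"] <- 0.1
  decoys$in_segdup[fail == "segdup"] <- TRUE
  decoys$local_db_count[fail == "local_db"] <- 10L
  decoys$pedigree_count[fail == "pedigree"] <- 10L
  decoys$flagged_control_db[fail == "flagged"] <- TRUE
  decoys$indel_len[fail == "indel_len"] <- 10L
  list(variants = variant_table(rbind(base, decoys)),
       passing_ids = base$variant_id, decoy_fail = fail)
}

# Filter configuration with one named filter disabled.
cfg_without <- function(which) {
  switch(which,
         popmax = filter_config(popmax_max = 1),
         qual = filter_config(qual_min = -Inf),
         mq = filter_config(mq_min = -Inf),
         mq_rank_sum = filter_config(mqrs_min = -Inf),
         ad_ratio = filter_config(ad_ratio_min = 0),
         segdup = filter_config(exclude_segdup = FALSE),
         local_db = filter_config(local_db_max = Inf),
         pedigree = filter_config(pedigree_max = Inf),
         flagged = filter_config(exclude_flagged = FALSE),
         indel_len = filter_config(indel_len_max = Inf))
}

# Brute-force one-sided (greater) Fisher tail by direct enumeration of the
# hypergeometric support with binomial coefficients; independent of phyper.
fisher_tail_oracle <- function(a, b, cc, d) {
  N <- a + b + cc + d
  K <- a + cc      # total carriers
  n1 <- a + b      # cases drawn
  lo <- max(0, K - (N - n1))
  hi <- min(K, n1)
  x <- lo:hi
  pr <- exp(lchoose(K, x) + lchoose(N - K, n1 - x) - lchoose(N, n1))
  sum(pr[x >= a])
}
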