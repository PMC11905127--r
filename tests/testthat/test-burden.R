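test_that("the filter cascade retains exactly the constructed passing set", {
  fx <- variant_fixture()
  kept <- filter_variants(fx$variants, filter_config(), "PTV")
  expect_setequal(kept$variant_id, fx$passing_ids)
  # removing any single filter admits exactly one decoy
  for (f in filter_names()) {
    relaxed <- filter_variants(fx$variants, cfg_without(f), "PTV")
    expect_equal(nrow(relaxed), 11)
    expect_length(setdiff(relaxed$variant_id, fx$passing_ids), 1)
  }
})

test_that("class gates and thresholds behave exactly", {
  v <- variant_table(data.frame(
    variant_id = paste0("v", 1:4), gene = "G1", cohort = "case",
    subject_id = paste0("S", 1:4),
    consequence = c("synonymous", "stop_gain", "spliceai_predicted",
                    "spliceai_predicted"),
    popmax_af = c(NA, 2e-4, NA, NA), qual = 99, mq = 60, mq_rank_sum = 0,
    ad_ratio = 0.5, in_segdup = FALSE, local_db_count = 0L,
    pedigree_count = 0L, flagged_control_db = FALSE, indel_len = 0L,
    allele_count = NA, spliceai_score = c(NA, NA, 0.9, 0.3),
    stringsAsFactors = FALSE))
  ptv <- filter_variants(v, filter_config(), "PTV")
  # synonymous excluded from PTV; popmax 2e-4 > 1e-4 excluded;
  # splice prediction qualifies only at score >= 0.5
  expect_equal(ptv$variant_id, "v3")
  syn <- filter_variants(v, filter_config(), "synonymous")
  expect_equal(syn$variant_id, "v1")
  expect_error(filter_variants(v, filter_config(), "missense"))
})

test_that("filtering is idempotent", {
  fx <- variant_fixture()
  once <- filter_variants(fx$variants, filter_config(), "PTV")
  twice <- filter_variants(once, filter_config(), "PTV")
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("carrier counting is per-subject for cases, capped for controls", {
  v <- variant_table(data.frame(
    variant_id = paste0("v", 1:5), gene = c("G1", "G2", "G3", "G1", "G2"),
    cohort = c("case", "case", "case", "control", "control"),
    subject_id = c("S1", "S1", "S1", NA, NA),
    consequence = "stop_gain",
    allele_count = c(NA, NA, NA, 40L, 20L), stringsAsFactors = FALSE))
  t1 <- build_contingency(v, c("G1", "G2", "G3"), n_cases = 100,
                          n_controls = 50)
  expect_equal(t1$a, 1)   # one subject, three qualifying variants
  expect_equal(t1$b, 99)
  expect_equal(t1$c, 50)  # 60 control alleles capped at n_controls
  expect_equal(t1$d, 0)

  t2 <- build_contingency(v[0, ], c("G1"), n_cases = 10, n_controls = 20)
  expect_equal(unlist(t2[c("a", "b", "c", "d")]),
               c(a = 0, b = 10, c = 0, d = 20))
  expect_error(build_contingency(v, c("G1", "G2", "G3"), n_cases = 0,
                                 n_controls = 50), "more case carriers")
})

test_that("Fisher p, odds ratio and Woolf interval match direct evaluation", {
  t0 <- list(a = 10, b = 10, c = 10, d = 10)
  f0 <- fisher_or_ci(t0)
  expect_equal(f0$or_hat, 1)
  expect_gt(f0$fisher_p, 0.5)
  expect_equal(log(f0$ci_high) + log(f0$ci_low), 0, tolerance = 1e-12)

  f1 <- fisher_or_ci(list(a = 0, b = 100, c = 5, d = 995))
  expect_equal(f1$fisher_p, 1)

  t <- list(a = 5, b = 95, c = 10, d = 9990)
  f <- fisher_or_ci(t)
  expect_equal(f$fisher_p, fisher_tail_oracle(5, 95, 10, 9990),
               tolerance = 1e-12)
  # no zero cell: raw counts in the Woolf formula
  or <- (5 * 9990) / (95 * 10)
  se <- sqrt(1 / 5 + 1 / 95 + 1 / 10 + 1 / 9990)
  expect_equal(f$or_hat, or, tolerance = 1e-12)
  expect_equal(f$ci_low, exp(log(or) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(f$ci_high, exp(log(or) + qnorm(0.975) * se), tolerance = 1e-12)
  # independent library route agrees on the exact tail
  ft <- fisher.test(matrix(c(5, 95, 10, 9990), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(f$fisher_p, ft$p.value, tolerance = 1e-9)

  # Haldane correction only fires on zero cells, and only for the OR/CI
  fz <- fisher_or_ci(list(a = 0, b = 100, c = 5, d = 995))
  expect_equal(fz$or_hat, (0.5 * 995.5) / (100.5 * 5.5), tolerance = 1e-12)
  expect_error(fisher_or_ci(list(a = 0, b = 0, c = 1, d = 9)), "empty cohort")
})

test_that("the z comparison matches independent arithmetic and negates on swap", {
  t_eq <- fisher_or_ci(list(a = 12, b = 388, c = 50, d = 49950))
  z0 <- compare_or_z(t_eq, t_eq)
  expect_equal(z0$z, 0)
  expect_equal(z0$z_p, 0.5)

  ptv <- fisher_or_ci(list(a = 20, b = 380, c = 50, d = 49950))
  syn <- fisher_or_ci(list(a = 5, b = 395, c = 50, d = 49950))
  zz <- compare_or_z(ptv, syn)
  lo1 <- log((20 * 49950) / (380 * 50))
  lo2 <- log((5 * 49950) / (395 * 50))
  s1 <- sqrt(1 / 20 + 1 / 380 + 1 / 50 + 1 / 49950)
  s2 <- sqrt(1 / 5 + 1 / 395 + 1 / 50 + 1 / 49950)
  expect_equal(zz$z, (lo1 - lo2) / sqrt(s1^2 + s2^2), tolerance = 1e-12)
  expect_equal(zz$z_p, pnorm(zz$z, lower.tail = FALSE))
  expect_equal(compare_or_z(syn, ptv)$z, -zz$z, tolerance = 1e-12)
})

test_that("the collapsed burden pipeline retains the planted trajectory only", {
  sets <- gene_set_collection(list(Tup = paste0("A", 1:15),
                                   Tnull = paste0("B", 1:15)))
  sim <- simulate_variants(sets, planted_or = c(Tup = 8), n_cases = 400,
                           n_controls = 50000, qc_fail_fraction = 0.5,
                           seed = 4)
  cases <- sim$variants[sim$variants$cohort == "case", ]
  ctrls <- sim$variants[sim$variants$cohort == "control", ]
  class(cases) <- class(ctrls) <- class(sim$variants)
  res <- run_burden(cases, ctrls, sets, filter_config(), 400, 50000)
  expect_equal(nrow(res), 4)  # 2 sets x {PTV, synonymous}
  up <- res[res$set_name == "Tup" & res$class == "PTV", ]
  expect_true(up$retained)
  expect_true(up$ci_low <= 8 & 8 <= up$ci_high)
  expect_equal(up$bonferroni_p, min(1, up$fisher_p * 2))
  nl <- res[res$set_name == "Tnull" & res$class == "PTV", ]
  expect_false(nl$retained)
  expect_identical(run_burden(cases, ctrls, gene_set_collection(list()),
                              filter_config(), 400, 50000)$set_name,
                   character())
})

test_that("synonymous-only enrichment is rejected by the z filter", {
  sets <- gene_set_collection(list(Tsyn = paste0("C", 1:15)))
  sim <- simulate_variants(sets, planted_or_syn = c(Tsyn = 8), n_cases = 400,
                           n_controls = 50000, seed = 5)
  cases <- sim$variants[sim$variants$cohort == "case", ]
  ctrls <- sim$variants[sim$variants$cohort == "control", ]
  class(cases) <- class(ctrls) <- class(sim$variants)
  res <- run_burden(cases, ctrls, sets, filter_config(), 400, 50000)
  expect_false(res$retained[res$class == "PTV"])
})

test_that("subphenotype strata are tested separately", {
  sets <- gene_set_collection(list(Tup = paste0("A", 1:15)))
  sim <- simulate_variants(sets, planted_or = c(Tup = 8), n_cases = 400,
                           n_controls = 50000, seed = 6)
  cases <- sim$variants[sim$variants$cohort == "case", ]
  ctrls <- sim$variants[sim$variants$cohort == "control", ]
  class(cases) <- class(ctrls) <- class(sim$variants)
  subph <- setNames(rep(c("KS", "nCHH"), each = 200), sprintf("S%04d", 1:400))
  res <- run_burden(cases, ctrls, sets, filter_config(), 400, 50000,
                    subphenotypes = subph)
  expect_setequal(unique(res$stratum), c("all", "KS", "nCHH"))
  ks <- res[res$stratum == "KS" & res$class == "PTV", ]
  expect_equal(ks$a + ks$b, 200)
})
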