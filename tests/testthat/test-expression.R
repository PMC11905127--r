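test_that("composition factors are 1 under symmetry and ignore pure scaling", {
  design <- tiny_design()[1:4, ]
  base <- matrix(rep(c(10L, 100L, 1000L, 50L, 500L), 4), 5, 4,
                 dimnames = list(paste0("G", 1:5), design$sample_id))
  x <- count_matrix(base, design)
  nf <- normalization_factors(x)
  expect_equal(unname(nf$comp_factor), rep(1, 4))

  scaled <- base
  scaled[, 2] <- base[, 2] * 2L
  y <- count_matrix(scaled, design)
  nf2 <- normalization_factors(y)
  expect_equal(unname(nf2$comp_factor), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(nf2$lib_size[2] / nf2$lib_size[1]), 2)

  z <- count_matrix(matrix(c(0L, 0L, 1L, 2L), 2, 2,
                           dimnames = list(c("A", "B"),
                                           design$sample_id[1:2])),
                    design[1:2, ])
  expect_error(normalization_factors(z), "all-zero sample")
})

test_that("trimmed-mean factor matches an independent re-implementation", {
  set.seed(42)
  design <- tiny_design(2)[1:6, ]
  m <- matrix(rpois(600, 200), 100, 6,
              dimnames = list(sprintf("G%03d", 1:100), design$sample_id))
  m[1, 3] <- m[1, 3] * 10L  # one inflated gene in one sample
  x <- count_matrix(m, design)
  nf <- normalization_factors(x)
  ref <- match(nf$ref_sample, colnames(m))

  # independent oracle: explicit sort-based double trim of M over proportions
  oracle <- vapply(1:6, function(j) {
    pj <- m[, j] / sum(m[, j]); pr <- m[, ref] / sum(m[, ref])
    keep <- pj > 0 & pr > 0
    M <- log2(pj[keep] / pr[keep])
    A <- 0.5 * log2(pj[keep] * pr[keep])
    n <- length(M)
    om <- order(M); oa <- order(A)
    in_m <- seq_len(n) %in% om[(floor(n * 0.3) + 1):(n - floor(n * 0.3))]
    in_a <- seq_len(n) %in% oa[(floor(n * 0.05) + 1):(n - floor(n * 0.05))]
    if (max(abs(M)) < 1e-10) 1 else 2^mean(M[in_m & in_a])
  }, numeric(1))
  oracle <- 1 / oracle
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(nf$comp_factor), unname(oracle), tolerance = 1e-10)
  # the inflated sample is pushed up by composition correction
  expect_gt(nf$comp_factor[3], 1)
})

test_that("dispersion estimation recovers the truth across regimes", {
  # Poisson data: estimates collapse toward zero
  design <- tiny_design(4)
  pos <- design[design$fraction == "GFP+", ]
  set.seed(7)
  mu <- exp(rnorm(2000, 5, 1))
  m <- matrix(rpois(2000 * 16, rep(mu, 16)), 2000, 16,
              dimnames = list(sprintf("G%04d", 1:2000), pos$sample_id))
  x <- count_matrix(m, pos)
  phi <- estimate_dispersion(x)
  expect_lte(median(phi), 0.01)

  # NB at phi = 0.1: median lands within the expected band
  p <- sim_params(n_genes = 2000, replicates_per_condition = 4, seed = 9)
  sim <- simulate_counts(p)
  xs <- subset_counts(sim$counts,
                      samples = sim$counts$design$sample_id[
                        sim$counts$design$fraction == "GFP+"])
  phi2 <- estimate_dispersion(xs)
  expect_gte(median(phi2), 0.07)
  expect_lte(median(phi2), 0.13)

  # identical counts in all replicates: zero residual variance, floor
  flat <- matrix(rep(c(5L, 50L, 500L), 16), 3, 16, byrow = FALSE,
                 dimnames = list(c("A", "B", "C"), pos$sample_id))
  xf <- count_matrix(flat, pos)
  phif <- estimate_dispersion(xf)
  expect_equal(unname(phif), rep(1e-4, 3), ignore_attr = TRUE)

  one <- count_matrix(matrix(1:3, 3, 1, dimnames = list(c("A", "B", "C"),
                                                        "s01")),
                      tiny_design()[1, ])
  expect_error(estimate_dispersion(one, groups = "g1"), "no replication")
})

test_that("exact test is invariant to sample order and pure scaling", {
  p <- sim_params(n_genes = 120, seed = 4)
  sim <- simulate_counts(p, c("+00" = 10))
  x <- sim$counts
  d1 <- de_test(x, "tau1")

  set.seed(1)
  perm <- sample(ncol(x$counts))
  xp <- count_matrix(x$counts[, perm], x$design[perm, ])
  d2 <- de_test(xp, "tau1")
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d1$pvalue, d2$pvalue, tolerance = 1e-12)

  # truly proportional columns: fold changes are zero and unaffected by
  # integer scaling of one sample
  design <- tiny_design(2)
  pos <- design[design$fraction == "GFP+", ]
  base <- c(20L, 200L, 2000L, 100L, 40L)
  m <- outer(base, rep(1L, 8))
  dimnames(m) <- list(paste0("G", 1:5), pos$sample_id)
  m2 <- m; m2[, 3] <- m2[, 3] * 3L
  r1 <- de_test(count_matrix(m, pos), "tau1")
  r2 <- de_test(count_matrix(m2, pos), "tau1")
  expect_lt(max(abs(r1$log2fc - r2$log2fc)), 1e-6)
  expect_lt(max(abs(r1$log2fc)), 1e-6)
})

test_that("FDR column is the Benjamini-Hochberg step-up of the p-values", {
  p <- sim_params(n_genes = 200, seed = 6)
  sim <- simulate_counts(p, c("+00" = 15))
  d <- de_test(sim$counts, "tau1")
  # independent step-up oracle
  n <- nrow(d)
  o <- order(d$pvalue)
  stepped <- pmin(d$pvalue[o] * n / seq_len(n), 1)
  stepped <- rev(cummin(rev(stepped)))
  expect_equal(d$fdr[o], stepped, tolerance = 1e-12)
  # the frozen textbook case: (0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03)
  pv <- c(0.01, 0.02, 0.03)
  manual <- rev(cummin(rev(pmin(pv * 3 / 1:3, 1))))
  expect_equal(manual, c(0.03, 0.03, 0.03))
  expect_equal(stats::p.adjust(pv, "BH"), manual)
  # monotone nondecreasing in p-value rank, bounded by 1
  expect_true(all(diff(d$fdr[o]) >= -1e-15))
  expect_true(all(d$fdr <= 1))
})

test_that("a planted 2.5-fold gene is detected in most simulations", {
  # Direction-balanced panel so composition normalization is unbiased. The
  # detection rule (FDR < 0.05 AND |log2fc| > 1) is bounded above by
  # P(|log2fc estimate| > 1) ~ 0.83 at fold 2.5, 4 replicates, phi = 0.1
  # (the estimate has SD ~ 0.33 in log2 units); the realized joint rate at
  # these generative conditions is ~ 0.77.
  hits <- 0; tot <- 0; sims <- 200
  for (s in seq_len(sims)) {
    p <- sim_params(n_genes = 100, seed = 1000 + s)
    sim <- simulate_counts(p, c("+00" = 5, "-00" = 5))
    x <- sim$counts
    pos <- subset_counts(x, samples = x$design$sample_id[
      x$design$fraction == "GFP+"])
    phi <- estimate_dispersion(pos, groups = as.character(pos$design$stage))
    d <- de_test(x, "tau1", dispersion = phi)
    planted <- sim$truth$gene[sim$truth$code != "000"]
    row <- d[d$gene %in% planted, ]
    hits <- hits + sum(row$fdr < 0.05 & abs(row$log2fc) > 1)
    tot <- tot + length(planted)
  }
  expect_gte(hits / tot, 0.7)
})

test_that("significant_genes applies both thresholds", {
  d <- data.frame(gene = c("A", "B", "C"), transition = "tau1",
                  log2fc = c(1.2, 0.9, -1.5), pvalue = c(0.001, 0.001, 0.2),
                  fdr = c(0.04, 0.04, 0.2), mean_cpm = 10)
  expect_setequal(significant_genes(d), "A")
  expect_length(significant_genes(d[0, ]), 0)
  expect_error(de_test(simulate_counts(sim_params(n_genes = 20))$counts,
                       "tau9"), "unknown transition")
})
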