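test_that("buffering calls match their definition and the equal-TE tie", {
  pd <- data.frame(
    rd_mrna = c(0.5, 0.2, 0.4),
    rd_rf = c(0.2, 0.5, 0.4),
    fd_te = c(3, 1.5, 1))
  calls <- classify_buffering(pd)
  expect_equal(calls$call, c("buffered", "reinforced", "tie"))
  expect_equal(calls$eligible_2fold, c(TRUE, FALSE, FALSE))
  # equal TE forces RD_RF = RD_mRNA -> tie
  m1 <- 6; m2 <- 2; te <- 2  # power of two keeps the identity exact in floats
  pd2 <- data.frame(rd_mrna = relative_divergence(m1, m2),
                    rd_rf = relative_divergence(m1 * te, m2 * te),
                    fd_te = 1)
  expect_equal(classify_buffering(pd2)$call, "tie")
})

test_that("buffering agrees with the log-ratio oracle on random pairs", {
  set.seed(77)
  n <- 20000
  m1 <- rlnorm(n, 2, 1.5); m2 <- rlnorm(n, 2, 1.5)
  te1 <- rlnorm(n, 0, 0.6); te2 <- rlnorm(n, 0, 0.6)
  r1 <- m1 * te1; r2 <- m2 * te2
  pd <- data.frame(rd_mrna = relative_divergence(m1, m2),
                   rd_rf = relative_divergence(r1, r2),
                   fd_te = fold_difference(te1, te2))
  calls <- classify_buffering(pd)$call
  expect_equal(calls, oracle_buffering_call(m1, m2, r1, r2))
})

test_that("binomial directionality test equals the enumeration oracle", {
  expect_equal(binomial_directionality_test(5, 10), 1)
  expect_equal(binomial_directionality_test(10, 10), 2 / 1024)
  expect_equal(binomial_directionality_test(7, 10), 0.34375)
  expect_true(is.na(binomial_directionality_test(0, 0)))
  for (n in c(1, 4, 9, 15)) for (k in 0:n)
    expect_equal(binomial_directionality_test(k, n),
                 oracle_binom_two_sided(k, n), tolerance = 1e-12)
})

test_that("Pearson correlation helper behaves at the boundaries", {
  x <- c(0.1, -0.3, 0.5, 0.2, -0.4)
  res <- correlate_divergences(x, -x)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_error(correlate_divergences(x, rep(0, 5)), "variance")
  expect_error(correlate_divergences(x[1:2], x[1:2]), "at least 3")
  set.seed(12)
  y <- 2 * x + rnorm(5, 0, 0.01)
  expect_gt(correlate_divergences(x, y)$r, 0.9)
})

test_that("fold-difference contrast counts, tests and handles degeneracy", {
  fd <- c(2, 3, 1.5, 8, 4)
  same <- compare_fold_differences(fd, fd)
  expect_equal(same$n_informative, 0)
  expect_true(is.na(same$wilcoxon_p))
  dbl <- compare_fold_differences(2 * rep(2, 50), rep(2, 50))
  expect_equal(dbl$n_mrna_greater, 50)
  expect_equal(dbl$binom_p, 2 * (1 / 2)^50)
  expect_lt(dbl$wilcoxon_p, 1e-9)
  set.seed(9)
  a <- rlnorm(40, 1, 0.4); b <- a * rlnorm(40, 0.5, 0.1)
  res <- compare_fold_differences(b, a)
  expect_gt(res$n_mrna_greater, res$n_te_greater)
  expect_lt(res$wilcoxon_p, 0.01)
})

test_that("Wilcoxon p-values are roughly uniform under a symmetric null", {
  set.seed(33)
  ps <- replicate(200, {
    d <- rnorm(30)
    compare_fold_differences(2^d, rep(1, 30))$wilcoxon_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(55)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("feature-divergence correlations recover planted coupling", {
  set.seed(45)
  n <- 400
  rd_te <- runif(n, -0.8, 0.8)
  feats <- data.frame(
    gc = rd_te + rnorm(n, 0, 0.2),        # planted positive coupling
    len = rnorm(n),                        # independent
    identical = rd_te)
  tab <- feature_divergence_correlations(feats, rd_te)
  expect_equal(tab$r[tab$feature == "identical"], 1, tolerance = 1e-12)
  expect_gt(tab$r[tab$feature == "gc"], 0.5)
  ci <- cor.test(feats$len, rd_te)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("split-replicate control equals the full estimate on clean data", {
  p <- sim_params(n_pairs = 300, dispersion = 0, libsize = 1e9, seed = 61)
  ds <- simulate_te_dataset(p, prop_diffte = 0)
  split <- split_replicate_control(ds$pairs, ds$counts$mrna_c1,
                                   ds$counts$ribo_c1, ds$lengths)
  mrna <- average_replicates(fpkm_from_counts(ds$counts$mrna_c1, ds$lengths))
  ribo <- average_replicates(fpkm_from_counts(ds$counts$ribo_c1, ds$lengths))
  pd <- pair_divergence_table(ds$pairs, mrna, ribo)
  full <- correlate_divergences(pd$rd_mrna[pd$pass], pd$rd_te[pd$pass])
  # at huge library size the count noise is negligible on both routes
  expect_equal(split$r, full$r, tolerance = 0.02)
  expect_error(split_replicate_control(ds$pairs,
                                       ds$counts$mrna_c1[, 1, drop = FALSE],
                                       ds$counts$ribo_c1, ds$lengths),
               ">= 2")
})

test_that("split control removes the ratio-coupling artifact when beta = 0", {
  p <- sim_params(n_pairs = 1500, beta = 0, sigma_t = 0.05, dispersion = 0.3,
                  libsize = 2e6, n_reps = 4, seed = 71)
  ds <- simulate_te_dataset(p, prop_diffte = 0)
  mrna <- average_replicates(fpkm_from_counts(ds$counts$mrna_c1, ds$lengths))
  ribo <- average_replicates(fpkm_from_counts(ds$counts$ribo_c1, ds$lengths))
  pd <- pair_divergence_table(ds$pairs, mrna, ribo)
  full <- correlate_divergences(pd$rd_mrna[pd$pass], pd$rd_te[pd$pass])
  split <- split_replicate_control(ds$pairs, ds$counts$mrna_c1,
                                   ds$counts$ribo_c1, ds$lengths)
  # shared mRNA noise biases the naive estimate negative; the split does not
  expect_lt(full$r, -0.05)
  expect_gt(split$r, full$r)
  expect_lt(abs(split$r), 0.08)
})

test_that("buffering summary separates the all and 2-fold subsets", {
  p <- sim_params(n_pairs = 1000, seed = 81)
  tr <- simulate_pair_expression(p)$truth
  pd <- truth_pair_div(tr)
  calls <- classify_buffering(pd)
  s <- buffering_summary(calls)
  expect_equal(s$subset, c("all", "te_fold_ge_2"))
  expect_equal(s$n_buffered + s$n_reinforced + s$n_ties, s$n_pairs)
  expect_gt(s$buffered_fraction[1], 0.5)
  expect_gte(s$buffered_fraction[2], s$buffered_fraction[1])
})
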