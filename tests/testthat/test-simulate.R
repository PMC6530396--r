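test_that("sim_params validates its inputs", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(sigma_d = -1), "sigma")
  expect_error(sim_params(dispersion = -0.1), "dispersion")
  expect_error(sim_params(n_pairs = 0), "n_pairs")
  expect_error(sim_params(mu0 = Inf), "non-finite")
})

test_that("pair expression simulator obeys its generative identities", {
  p <- sim_params(n_pairs = 200, seed = 11)
  s <- simulate_pair_expression(p)
  tr <- s$truth
  # RF FPKM is exactly mRNA FPKM x TE
  expect_equal(tr$rf1, tr$mrna1 * tr$te1, tolerance = 1e-14)
  expect_equal(tr$rf2, tr$mrna2 * tr$te2, tolerance = 1e-14)
  # symmetric split: pair log-sum independent of divergence direction
  expect_equal(log2(tr$mrna1) + log2(tr$mrna2), 2 * tr$mu, tolerance = 1e-10)
  # determinism
  s2 <- simulate_pair_expression(p)
  expect_identical(s, s2)
})

test_that("degenerate generator settings collapse the divergences", {
  s0 <- simulate_pair_expression(
    sim_params(n_pairs = 100, beta = 0, sigma_t = 0, seed = 2))
  expect_equal(s0$truth$te1, s0$truth$te2)
  expect_equal(s0$truth$rd_rf, s0$truth$rd_mrna, tolerance = 1e-12)
  sflat <- simulate_pair_expression(
    sim_params(n_pairs = 100, sigma_d = 0, sigma_t = 0, seed = 2))
  expect_true(all(abs(sflat$truth$rd_mrna) < 1e-12))
  expect_true(all(abs(sflat$truth$rd_te) < 1e-12))
  expect_true(all(abs(sflat$truth$rd_rf) < 1e-12))
})

test_that("buffering coefficient induces negative mRNA/TE divergence coupling", {
  s <- simulate_pair_expression(
    sim_params(n_pairs = 2000, beta = 0.5, sigma_d = 1, sigma_t = 0.3, seed = 5))
  expect_lt(cor(s$truth$rd_mrna, s$truth$rd_te), -0.5)
  # buffered majority under beta > 0 with small TE noise
  frac <- mean(abs(s$truth$rd_rf) < abs(s$truth$rd_mrna))
  expect_gt(frac, 0.5)
})

test_that("count simulator matches NB moments and handles edge cases", {
  p <- sim_params(n_pairs = 1, n_reps = 1, dispersion = 0, libsize = 1e6,
                  gene_length_bp = 1000, seed = 3)
  expect_true(all(simulate_counts(c(a = 0, b = 0), p) == 0))
  # Poisson limit: fpkm=50 at these settings means m=50
  p2 <- sim_params(n_pairs = 1, n_reps = 20000, dispersion = 0, libsize = 1e6,
                   gene_length_bp = 1000, seed = 4)
  x <- as.numeric(simulate_counts(c(g = 50), p2))
  expect_equal(mean(x), 50, tolerance = 0.02)
  expect_equal(var(x), mean(x), tolerance = 0.05)
  # NB variance m + phi m^2
  p3 <- sim_params(n_pairs = 1, n_reps = 20000, dispersion = 0.2,
                   libsize = 1e6, gene_length_bp = 1000, seed = 5)
  y <- as.numeric(simulate_counts(c(g = 100), p3))
  expect_equal(var(y), 100 + 0.2 * 100^2, tolerance = 0.08)
  expect_error(simulate_counts(c(g = -1), p3), ">= 0")
  expect_identical(simulate_counts(c(g = 10), p3),
                   simulate_counts(c(g = 10), p3))
})

test_that("two-condition dataset plants differential TE where claimed", {
  p <- sim_params(n_pairs = 150, seed = 8)
  ds <- simulate_te_dataset(p, n_singletons = 30, prop_diffte = 0.2,
                            te_log2fc = 2, prop_diffte_singleton = 0.05)
  gt <- ds$gene_truth
  expect_equal(nrow(gt), 330)
  shifted <- gt$te_c2 / gt$te_c1
  expect_true(all(abs(shifted[gt$diffte] - 4) < 1e-12))
  expect_true(all(abs(shifted[!gt$diffte] - 1) < 1e-12))
  expect_identical(names(ds$counts),
                   c("mrna_c1", "ribo_c1", "mrna_c2", "ribo_c2"))
  expect_true(all(vapply(ds$counts, ncol, integer(1)) == p$n_reps))
})

test_that("annotation simulator encodes the planted tandem geometry", {
  planted <- data.frame(
    family_id = c("FA", "FB", "FC", "FD"),
    n_members = 2,
    intervening = c(5, 11, 3, 0),
    span_bp = c(50000, 60000, 150000, 40000),
    same_chrom = c(TRUE, TRUE, TRUE, FALSE))
  sim <- simulate_gene_annotation(n_chrom = 2, n_genes = 40,
                                  planted_clusters = planted, seed = 9)
  tr <- sim$truth
  expect_equal(tr$tandem_eligible, c(TRUE, FALSE, FALSE, FALSE))
  ann <- sim$annotation
  # planted members really are separated by the requested gene count
  for (i in seq_len(nrow(tr))) {
    mem <- strsplit(tr$members[i], ",")[[1]]
    rows <- ann[match(mem, ann$gene_id), ]
    if (!tr$same_chrom[i]) {
      expect_gt(length(unique(rows$chrom)), 1)
      next
    }
    between <- sum(ann$chrom == rows$chrom[1] &
                     ann$start > min(rows$start) & ann$start < max(rows$start))
    expect_equal(between, tr$intervening[i])
    expect_equal(diff(range(rows$start)), tr$span_bp[i])
  }
  expect_error(
    simulate_gene_annotation(planted_clusters = data.frame(
      family_id = "FX", n_members = 2, intervening = 50, span_bp = 60)),
    "cannot host")
})

test_that("triplet simulator respects branch lengths and avoids stops", {
  t0 <- simulate_triplet_sequences(0, 0, 0, 50, seed = 1)
  expect_equal(unname(t0$seqs[1]), unname(t0$seqs[2]))
  expect_equal(unname(t0$seqs[1]), unname(t0$seqs[3]))
  t1 <- simulate_triplet_sequences(0.3, 0.05, 0.4, 2000, seed = 6)
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  for (s in t1$seqs)
    expect_false(any(Biostrings::GENETIC_CODE[codons(s)] == "*"))
  # longer branch accrues more differences from the outgroup
  ndiff <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_gt(ndiff(t1$seqs[[1]], t1$seqs[[3]]), ndiff(t1$seqs[[2]], t1$seqs[[3]]))
  expect_identical(simulate_triplet_sequences(0.3, 0.05, 0.4, 100, seed = 6),
                   simulate_triplet_sequences(0.3, 0.05, 0.4, 100, seed = 6))
})

test_that("triplet FASTA round-trips", {
  tri <- simulate_triplet_sequences(0.1, 0.1, 0.3, 40, seed = 2)
  f <- tempfile(fileext = ".fasta")
  write_triplet_fasta(tri, f)
  back <- read_triplet_fasta(f)
  expect_equal(unname(back$seqs), unname(tri$seqs))
  expect_equal(back$n_codons, 40)
})
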