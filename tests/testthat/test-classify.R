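test_that("longest isoform is selected, ties broken lexicographically", {
  models <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    isoform_id = c("g1.2", "g1.1", "g2.1", "g3.b", "g3.a"),
    cds_length = c(450, 300, 120, 300, 300))
  rep <- select_representative_isoform(models)
  expect_equal(rep$isoform_id[rep$gene_id == "g1"], "g1.2")
  expect_equal(rep$isoform_id[rep$gene_id == "g2"], "g2.1")
  expect_equal(rep$isoform_id[rep$gene_id == "g3"], "g3.a")
  # length can come from the sequence itself
  seqs <- data.frame(gene_id = "g", isoform_id = c("i1", "i2"),
                     cds_sequence = c("ATGATG", "ATG"))
  expect_equal(select_representative_isoform(seqs)$isoform_id, "i1")
})

make_ann <- function(starts, fams, chrom = "chr1", extra = NULL) {
  ann <- data.frame(
    gene_id = sprintf("g%02d", seq_along(starts)), chrom = chrom,
    start = starts, end = starts + 100, strand = "+", family_id = fams,
    stringsAsFactors = FALSE)
  rbind(ann, extra)
}

test_that("tandem clustering applies the intervening/span/chromosome rules", {
  # two family-F genes, 5 intervening, 50 kb apart -> one cluster
  ann <- make_ann(c(0:6) * 8000 + 1, c("F", paste0("x", 1:5), "F"))
  cl <- cluster_tandem(ann)
  f_cl <- cl$cluster_id[cl$family_id == "F"]
  expect_equal(length(unique(f_cl)), 1)
  # 11 intervening genes -> two singleton clusters
  ann2 <- make_ann(c(0:12) * 5000 + 1, c("F", paste0("x", 1:11), "F"))
  cl2 <- cluster_tandem(ann2)
  expect_equal(length(unique(cl2$cluster_id[cl2$family_id == "F"])), 2)
  # >100 kb, few intervening genes -> not clustered
  ann3 <- make_ann(c(1, 50001, 100002, 150001),
                   c("F", "x1", "x2", "F"))
  cl3 <- cluster_tandem(ann3)
  expect_equal(length(unique(cl3$cluster_id[cl3$family_id == "F"])), 2)
  # different chromosomes never cluster
  ann4 <- data.frame(gene_id = c("a", "b"), chrom = c("chr1", "chr2"),
                     start = c(1, 100), end = c(50, 200), strand = "+",
                     family_id = "F")
  cl4 <- cluster_tandem(ann4)
  expect_equal(length(unique(cl4$cluster_id)), 2)
})

test_that("boundary values are inclusive: exactly 10 genes, exactly 100 kb", {
  ann_b1 <- make_ann(c(0:11) * 5000 + 1, c("F", paste0("x", 1:10), "F"))
  cl <- cluster_tandem(ann_b1)
  expect_equal(length(unique(cl$cluster_id[cl$family_id == "F"])), 1)
  ann_b2 <- make_ann(c(1, 100001), c("F", "F"))  # span exactly 100,000
  cl2 <- cluster_tandem(ann_b2)
  expect_equal(length(unique(cl2$cluster_id[cl2$family_id == "F"])), 1)
  ann_b3 <- make_ann(c(1, 100002), c("F", "F"))  # one past the boundary
  cl3 <- cluster_tandem(ann_b3)
  expect_equal(length(unique(cl3$cluster_id[cl3$family_id == "F"])), 2)
})

test_that("single-linkage chains clusters past the pairwise span", {
  # A-B and B-C each within 100 kb; A-C spans 150 kb -> one cluster {A,B,C}
  ann <- make_ann(c(1, 75001, 150001), c("F", "F", "F"))
  cl <- cluster_tandem(ann)
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(sort(cl$gene_id), c("g01", "g02", "g03"))
})

test_that("clustering is invariant to annotation row order", {
  set.seed(31)
  ann <- make_ann(sort(sample(1:500, 60)) * 1000,
                  sample(c("F1", "F2", "F3", paste0("u", 1:20)), 60, TRUE))
  cl_sorted <- cluster_tandem(ann)
  shuffled <- ann[sample(nrow(ann)), ]
  cl_shuffled <- cluster_tandem(shuffled)
  key <- function(cl) {
    members <- split(cl$gene_id, cl$cluster_id)
    sort(vapply(members, function(g) paste(sort(g), collapse = ","), ""))
  }
  expect_equal(unname(key(cl_sorted)), unname(key(cl_shuffled)))
})

test_that("cluster representatives are stable, uniform and size-aware", {
  cl2 <- data.frame(gene_id = c("A", "B"), cluster_id = "TC1")
  expect_equal(choose_cluster_representatives(cl2)$gene1, "A")
  cl1 <- data.frame(gene_id = "A", cluster_id = "TC1")
  expect_equal(nrow(choose_cluster_representatives(cl1)), 0)
  cl3 <- data.frame(gene_id = c("A", "B", "C"), cluster_id = "TC1")
  expect_identical(choose_cluster_representatives(cl3, seed = 4),
                   choose_cluster_representatives(cl3, seed = 4))
  draws <- vapply(1:3000, function(s) {
    p <- choose_cluster_representatives(cl3, seed = s)
    paste(p$gene1, p$gene2)
  }, character(1))
  freq <- table(draws) / length(draws)
  expect_equal(length(freq), 3)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("gene classes follow the threshold precedence rules", {
  hits <- data.frame(
    query_id = c("o1", "u1", "w1", "self"),
    subject_id = c("zz", "zz", "zz", "self"),
    e_value = c(1e-12, 1e-5, 1e-40, 0))
  wgd <- data.frame(gene1 = "w1", gene2 = "w2")
  tan <- data.frame(gene1 = "t1", gene2 = "t2")
  cls <- classify_genes(c("w1", "w2", "t1", "o1", "u1", "s1", "self"),
                        hits, wgd, tan)
  got <- setNames(cls$class, cls$gene_id)
  expect_equal(got[["w1"]], "wgd")       # precedence over its strong hit
  expect_equal(got[["w2"]], "wgd")
  expect_equal(got[["t1"]], "tandem")
  expect_equal(got[["o1"]], "other")     # best E = 1e-12 <= 1e-10
  expect_equal(got[["u1"]], "unclassified")  # 1e-10 < 1e-5 <= 1e-3
  expect_equal(got[["s1"]], "singleton")  # no hits at all
  expect_equal(got[["self"]], "singleton")  # self-hits are ignored
  # every gene gets exactly one label
  expect_equal(nrow(cls), 7)
  expect_false(anyNA(cls$class))
})

test_that("sequence features handle ambiguity and degenerate input", {
  genes <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    cds_sequence = c("ATGC", "GGCC", "ATGNNC", "NNN"),
    stringsAsFactors = FALSE)
  f <- compute_sequence_features(genes)
  expect_equal(f$gc_cds, c(0.5, 1.0, 0.5, NA_real_))
  expect_equal(f$cds_length, c(4, 4, 6, 3))
  expect_error(compute_sequence_features(
    data.frame(gene_id = "x", cds_sequence = "ATXG")), "alphabet")
  with_utr <- compute_sequence_features(
    data.frame(gene_id = "a", cds_sequence = "ATGC",
               utr3_sequence = "AAAAA", mfe_3utr = -12.3))
  expect_equal(with_utr$utr3_length, 5)
  expect_equal(with_utr$mfe_3utr, -12.3)
})
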