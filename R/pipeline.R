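#' Pipeline run configuration
#'
#' Collects thresholds (defaulting to the standard printed values:
#' FPKM >= 0.1, TE fold >= 2, FDR 0.05, at most 10 intervening genes within
#' 100 kb, duplicate/singleton E-value cutoffs 1e-10 and 1e-3), simulation
#' parameters for the bundled synthetic fixture, and the output directory.
#' Any field can be overridden by name.
#'
#' @param seed Integer seed driving every stage.
#' @param out_dir Output directory (created if missing).
#' @param ... Overrides for any config field, e.g. `n_pairs`, `fpkm_min`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("dupribo_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    # fixture scale
    n_pairs = 400L, n_singletons = 150L,
    frac_wgd = 0.6, frac_tandem = 0.25,
    # expression generator (study conditions)
    mu0 = 4, sigma0 = 2, sigma_d = 1, beta = 0.5, sigma_t = 0.3, te0 = 1,
    n_reps = 3L, dispersion = 0.1, libsize = 2e7, gene_length_bp = 1500,
    prop_diffte = 0.15, te_log2fc = 2, prop_diffte_singleton = 0.05,
    # sequence-evolution fixture
    n_triplets = 120L, triplet_codons = 300L, asym_fraction = 0.3,
    b_sym = 0.1, b_asym = 0.3, b_out = 0.4,
    # thresholds
    fpkm_min = 0.1, te_fold_min = 2, fdr = 0.05,
    max_intervening = 10L, max_span_bp = 100000L,
    blast_dup_e = 1e-10, blast_single_e = 1e-3,
    min_codons = 30L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  thr <- c("fpkm_min", "te_fold_min", "fdr", "max_intervening",
           "max_span_bp", "blast_dup_e", "blast_single_e")
  if (any(unlist(cfg[thr]) <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file with config fields; missing fields take defaults.
#' @param ... Further overrides applied on top of the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(y, list(...)))
}

#' Validate pipeline inputs
#'
#' Cross-checks annotation, count matrices, gene lengths and pair lists
#' before any computation: id overlap, coordinate sanity, negative counts.
#'
#' @param annotation Annotation data frame (or NULL).
#' @param counts Named list of count matrices (or NULL).
#' @param pairs Pair data frame (or NULL).
#' @param lengths Named length vector (or NULL).
#' @return Data frame of diagnostics (`context`, `issue`); zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(annotation = NULL, counts = NULL, pairs = NULL,
                            lengths = NULL) {
  diag <- list()
  add <- function(context, issue)
    diag[[length(diag) + 1]] <<- data.frame(context = context, issue = issue,
                                            stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    if (any(annotation$start > annotation$end))
      add("annotation", sprintf("start > end for %d gene(s)",
                                sum(annotation$start > annotation$end)))
    if (any(annotation$start <= 0))
      add("annotation", sprintf("non-positive coordinate for %d gene(s)",
                                sum(annotation$start <= 0)))
    if (anyDuplicated(annotation$gene_id))
      add("annotation", "duplicated gene_id values")
  }
  if (!is.null(counts)) for (nm in names(counts)) {
    m <- counts[[nm]]
    if (any(m < 0)) add(nm, "negative counts")
    if (is.null(rownames(m))) add(nm, "count matrix lacks gene rownames")
    else if (!is.null(lengths) && !all(rownames(m) %in% names(lengths)))
      add(nm, sprintf("%d gene(s) missing from the length table",
                      sum(!rownames(m) %in% names(lengths))))
  }
  if (!is.null(pairs)) {
    if (any(pairs$gene1 == pairs$gene2))
      add("pairs", "pair with identical members")
    if (!is.null(annotation)) {
      absent <- setdiff(c(pairs$gene1, pairs$gene2), annotation$gene_id)
      if (length(absent))
        add("pairs", sprintf("%d pair gene id(s) absent from annotation (e.g. %s)",
                             length(absent), absent[1]))
    }
  }
  if (length(diag)) do.call(rbind, diag)
  else data.frame(context = character(), issue = character(),
                  stringsAsFactors = FALSE)
}

# deterministic annotation for the synthetic cohort: tandem-pair members are
# adjacent and share a family; every other gene gets its own family
build_cohort_annotation <- function(gene_truth, pairs) {
  genes <- gene_truth$gene_id
  tandem <- pairs[pairs$dup_type == "tandem", , drop = FALSE]
  tan_first <- stats::setNames(tandem$gene2, tandem$gene1)
  placed <- character(0); order_out <- character(0)
  for (g in genes) {
    if (g %in% placed) next
    order_out <- c(order_out, g)
    placed <- c(placed, g)
    if (g %in% names(tan_first) && !(tan_first[[g]] %in% placed)) {
      order_out <- c(order_out, tan_first[[g]])
      placed <- c(placed, tan_first[[g]])
    }
  }
  n <- length(order_out)
  per_chrom <- 100L
  # lay genes on a grid of slots; a tandem pair never straddles a chromosome
  slot <- integer(n); pos <- 0L; i <- 1L
  while (i <= n) {
    unit <- if (i < n && order_out[i] %in% names(tan_first) &&
                identical(order_out[i + 1], unname(tan_first[[order_out[i]]])))
      2L else 1L
    if (unit == 2L && (pos %% per_chrom) == per_chrom - 1L) pos <- pos + 1L
    slot[i] <- pos
    if (unit == 2L) slot[i + 1L] <- pos + 1L
    pos <- pos + unit; i <- i + unit
  }
  chrom <- sprintf("chr%d", slot %/% per_chrom + 1)
  start <- 10000 * ((slot %% per_chrom) + 1)
  fam <- order_out
  fam[match(tandem$gene2, order_out)] <- tandem$gene1
  data.frame(gene_id = order_out, chrom = chrom, start = start,
             end = start + 999, strand = "+", family_id = paste0("FAM_", fam),
             stringsAsFactors = FALSE)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulates a paralog cohort with known ground truth, then runs every
#' stage in order — duplicate classification, FPKM/TE quantification,
#' buffering and fold-difference statistics, Ka/Ks and clock LRT on
#' simulated triplets, and the differential-TE test across the two
#' simulated conditions — writing per-stage TSVs and a deterministic JSON
#' report to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  ## stage 1: simulate expression cohort
  params <- sim_params(
    n_pairs = config$n_pairs, mu0 = config$mu0, sigma0 = config$sigma0,
    sigma_d = config$sigma_d, beta = config$beta, sigma_t = config$sigma_t,
    te0 = config$te0, n_reps = config$n_reps, dispersion = config$dispersion,
    libsize = config$libsize, gene_length_bp = config$gene_length_bp,
    seed = config$seed)
  ds <- simulate_te_dataset(params, n_singletons = config$n_singletons,
                            prop_diffte = config$prop_diffte,
                            te_log2fc = config$te_log2fc,
                            prop_diffte_singleton = config$prop_diffte_singleton)
  n_wgd <- round(config$frac_wgd * config$n_pairs)
  n_tan <- round(config$frac_tandem * config$n_pairs)
  dup_type <- rep("other", config$n_pairs)
  dup_type[seq_len(n_wgd)] <- "wgd"
  if (n_tan > 0) dup_type[n_wgd + seq_len(n_tan)] <- "tandem"
  pairs <- cbind(ds$pairs, dup_type = dup_type, stringsAsFactors = FALSE)
  annotation <- build_cohort_annotation(ds$gene_truth, pairs)
  hits <- data.frame(query_id = pairs$gene1, subject_id = pairs$gene2,
                     e_value = 1e-50, stringsAsFactors = FALSE)
  diagnostics <- validate_inputs(annotation, ds$counts, pairs, ds$lengths)
  if (nrow(diagnostics)) {
    write_tsv(diagnostics, out("diagnostics.tsv"))
    stop("input validation failed; see ", out("diagnostics.tsv"))
  }
  for (nm in names(ds$counts)) write_count_tsv(ds$counts[[nm]],
                                               out(paste0("counts_", nm, ".tsv")))
  write_tsv(data.frame(gene_id = names(ds$lengths), length_bp = ds$lengths),
            out("lengths.tsv"))
  write_annotation_tsv(annotation, out("annotation.tsv"))
  write_tsv(ds$truth, out("truth_pairs.tsv"))

  ## stage 2: classification
  clusters <- cluster_tandem(annotation, config$max_intervening,
                             config$max_span_bp)
  tandem_pairs <- choose_cluster_representatives(clusters,
                                                 seed = config$seed + 3L)
  wgd_pairs <- pairs[pairs$dup_type == "wgd", c("gene1", "gene2")]
  classes <- classify_genes(ds$gene_truth$gene_id, hits, wgd_pairs,
                            tandem_pairs, config$blast_dup_e,
                            config$blast_single_e)
  write_tsv(clusters, out("tandem_clusters.tsv"))
  write_tsv(classes, out("gene_classes.tsv"))

  ## stage 3+4: quantification and divergence statistics per condition
  stats_by_cond <- list()
  pair_div_c1 <- NULL
  for (cond in c("c1", "c2")) {
    mrna <- fpkm_from_counts(ds$counts[[paste0("mrna_", cond)]], ds$lengths)
    ribo <- fpkm_from_counts(ds$counts[[paste0("ribo_", cond)]], ds$lengths)
    pd <- pair_divergence_table(pairs, average_replicates(mrna),
                                average_replicates(ribo), config$fpkm_min)
    pd$dup_type <- pairs$dup_type
    pd <- classify_buffering(pd, config$te_fold_min)
    write_tsv(pd, out(paste0("pair_divergence_", cond, ".tsv")))
    if (cond == "c1") pair_div_c1 <- pd
    ok <- pd$pass
    buf <- buffering_summary(pd)
    corr <- correlate_divergences(pd$rd_mrna[ok], pd$rd_te[ok])
    fdc <- compare_fold_differences(pd$fd_mrna[ok], pd$fd_te[ok])
    split <- split_replicate_control(
      pairs, ds$counts[[paste0("mrna_", cond)]],
      ds$counts[[paste0("ribo_", cond)]], ds$lengths, config$fpkm_min)
    stats_by_cond[[cond]] <- list(
      n_pairs_pass = sum(ok),
      buffered_fraction_all = buf$buffered_fraction[buf$subset == "all"],
      buffered_binom_p_all = buf$binom_p[buf$subset == "all"],
      buffered_fraction_te2fold =
        buf$buffered_fraction[buf$subset == "te_fold_ge_2"],
      buffered_binom_p_te2fold = buf$binom_p[buf$subset == "te_fold_ge_2"],
      pearson_r_rdmrna_rdte = corr$r, pearson_p_rdmrna_rdte = corr$p,
      wilcoxon_p_fd = fdc$wilcoxon_p,
      frac_mrna_fd_greater =
        fdc$n_mrna_greater / max(1, fdc$n_mrna_greater + fdc$n_te_greater),
      split_control_r = split$r, split_control_p = split$p)
  }

  ## stage 5: evolutionary rates on simulated triplets
  n_tr <- min(config$n_triplets, config$n_pairs)
  set.seed(config$seed + 4L)
  asym <- stats::runif(n_tr) < config$asym_fraction
  rates <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    if (asym[i]) {
      # plant the faster-evolving branch on the lower-RF copy
      gene2_higher <- !is.na(ds$truth$rd_rf[i]) && ds$truth$rd_rf[i] > 0
      b1 <- if (gene2_higher) config$b_asym else config$b_sym
      b2 <- if (gene2_higher) config$b_sym else config$b_asym
    } else b1 <- b2 <- config$b_sym
    tri <- simulate_triplet_sequences(b1, b2, config$b_out,
                                      config$triplet_codons,
                                      seed = config$seed + 1000L + i)
    re <- rate_estimates(tri, config$min_codons)
    re$pair_id <- ds$truth$pair_id[i]
    re$true_asym <- asym[i]
    rates[[i]] <- re
  }
  rates <- do.call(rbind, rates)
  write_tsv(rates, out("rate_estimates.tsv"))
  asym_sum <- asymmetry_summary(rates, pair_div_c1, config$fdr,
                                rf_fold_min = 1)

  ## stage 6: differential TE between conditions
  cmat <- cbind(ds$counts$mrna_c1, ds$counts$ribo_c1,
                ds$counts$mrna_c2, ds$counts$ribo_c2)
  colnames(cmat) <- paste0(rep(c("mrna_c1", "ribo_c1", "mrna_c2", "ribo_c2"),
                               each = config$n_reps),
                           "_r", seq_len(config$n_reps))
  design <- data.frame(
    assay = rep(rep(c("mrna", "ribo"), each = config$n_reps), 2),
    condition = rep(c("c1", "c2"), each = 2 * config$n_reps),
    # the generator scales every library to the same nominal depth; using
    # per-sample totals would fold the planted TE shifts into the offsets
    libsize = config$libsize)
  dte <- te_interaction_test(cmat, design, fdr = config$fdr)
  write_tsv(dte, out("diffte.tsv"))
  dsum <- pair_differential_summary(dte, pairs, classes)

  report <- list(
    seed = config$seed,
    n_pairs = config$n_pairs, n_singletons = config$n_singletons,
    class_counts = as.list(table(classes$class)),
    n_tandem_clusters_ge2 = sum(table(clusters$cluster_id) >= 2),
    conditions = stats_by_cond,
    asymmetry = asym_sum,
    diffte = list(
      n_tested = sum(dte$tested), n_flagged = sum(dte$flag),
      true_positive_rate =
        mean(dte$flag[ds$gene_truth$diffte & dte$tested]),
      pair_table = dsum$pair_table,
      enrichment_p = if (is.null(dsum$enrichment)) NA else dsum$enrichment$p))
  write_report_json(report, out("report.json"))
  invisible(report)
}
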