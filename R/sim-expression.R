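#' Simulation parameters for paired paralog expression
#'
#' Bundles the generative parameters for synthetic paralog-pair expression
#' data: per-pair base abundance, transcriptional divergence, a tunable
#' coupling between transcriptional and translational divergence, and the
#' negative-binomial count model used to produce replicate-level fragment
#' counts.
#'
#' The generative model is, per pair \eqn{i}:
#' \deqn{\mu_i \sim N(\mu_0, \sigma_0^2), \quad d_i \sim N(0, \sigma_d^2),
#'   \quad t_i = -\beta d_i + \epsilon_i, \ \epsilon_i \sim N(0, \sigma_t^2)}
#' where \eqn{d_i} is the log2 mRNA ratio (copy1/copy2) and \eqn{t_i} the
#' log2 TE ratio. `beta > 0` means translational efficiency opposes the
#' transcriptional divergence (translational buffering); `beta = 0` decouples
#' them.
#'
#' @param n_pairs Number of paralog pairs.
#' @param mu0,sigma0 Mean and sd of the base log2 FPKM \eqn{\mu_i}.
#' @param sigma_d Sd of the transcriptional log2 ratio \eqn{d_i}.
#' @param beta Buffering coefficient linking TE divergence to mRNA divergence.
#' @param sigma_t Sd of the TE-specific noise \eqn{\epsilon_i}.
#' @param te0 Baseline translational efficiency shared by both copies.
#' @param n_reps Replicates per assay and condition.
#' @param dispersion Negative-binomial dispersion \eqn{\phi}
#'   (\eqn{Var = m + \phi m^2}); 0 gives Poisson counts.
#' @param libsize Total mapped fragments per replicate library.
#' @param gene_length_bp Effective gene length in bp (shared by all genes).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_pairs = 2000, mu0 = 4, sigma0 = 2, sigma_d = 1,
                       beta = 0.5, sigma_t = 0.3, te0 = 1, n_reps = 3,
                       dispersion = 0.1, libsize = 2e7,
                       gene_length_bp = 1500, seed = 1L) {
  p <- list(n_pairs = as.integer(n_pairs), mu0 = mu0, sigma0 = sigma0,
            sigma_d = sigma_d, beta = beta, sigma_t = sigma_t, te0 = te0,
            n_reps = as.integer(n_reps), dispersion = dispersion,
            libsize = libsize, gene_length_bp = gene_length_bp,
            seed = as.integer(seed))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-finite or non-scalar simulation parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  if (p$sigma0 < 0 || p$sigma_d < 0 || p$sigma_t < 0)
    stop("sigma0, sigma_d and sigma_t must be >= 0")
  if (p$dispersion < 0) stop("dispersion must be >= 0")
  if (p$n_pairs < 1 || p$n_reps < 1) stop("n_pairs and n_reps must be >= 1")
  if (p$te0 <= 0) stop("te0 must be > 0")
  if (p$libsize <= 0 || p$gene_length_bp <= 0)
    stop("libsize and gene_length_bp must be > 0")
  structure(p, class = "sim_params")
}

#' Simulate true expression and translational efficiency for paralog pairs
#'
#' Draws the latent pair-level quantities and returns both the per-gene true
#' FPKM/TE table (the "expression" view) and a per-pair truth table carrying
#' the latent variables and the true signed relative divergences. Copy 1
#' gets mRNA FPKM \eqn{2^{\mu_i + d_i/2}} and copy 2 \eqn{2^{\mu_i - d_i/2}};
#' TEs split symmetrically as \eqn{TE_0 2^{\pm t_i/2}}; the true
#' ribosome-footprint (RF) FPKM is exactly mRNA FPKM times TE.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `expression` (data frame: gene_id, pair_id,
#'   copy, true mrna_fpkm, te, rf_fpkm) and `truth` (one row per pair with
#'   mu, d, t and the true relative divergences rd_mrna, rd_te, rd_rf).
#' @export
simulate_pair_expression <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_pairs
  mu <- stats::rnorm(n, params$mu0, params$sigma0)
  d  <- stats::rnorm(n, 0, params$sigma_d)
  t  <- -params$beta * d + stats::rnorm(n, 0, params$sigma_t)
  pair_id <- sprintf("P%05d", seq_len(n))
  mrna1 <- 2^(mu + d / 2); mrna2 <- 2^(mu - d / 2)
  te1 <- params$te0 * 2^(t / 2); te2 <- params$te0 * 2^(-t / 2)
  rf1 <- mrna1 * te1; rf2 <- mrna2 * te2
  truth <- data.frame(
    pair_id = pair_id,
    gene1 = paste0(pair_id, "a"), gene2 = paste0(pair_id, "b"),
    mu = mu, d = d, t = t,
    mrna1 = mrna1, mrna2 = mrna2, te1 = te1, te2 = te2,
    rf1 = rf1, rf2 = rf2,
    rd_mrna = relative_divergence(mrna1, mrna2),
    rd_te = relative_divergence(te1, te2),
    rd_rf = relative_divergence(rf1, rf2),
    stringsAsFactors = FALSE)
  expression <- data.frame(
    gene_id = c(truth$gene1, truth$gene2),
    pair_id = rep(pair_id, 2),
    copy = rep(1:2, each = n),
    mrna_fpkm = c(mrna1, mrna2),
    te = c(te1, te2),
    rf_fpkm = c(rf1, rf2),
    stringsAsFactors = FALSE)
  expression <- expression[order(expression$pair_id, expression$copy), ]
  rownames(expression) <- NULL
  list(expression = expression, truth = truth)
}

#' Simulate replicate fragment counts from true FPKM
#'
#' Converts true FPKM to an expected fragment count
#' \eqn{m = FPKM \times (L/1000) \times (libsize/10^6)} and draws `n_reps`
#' negative-binomial replicates per gene with \eqn{Var = m + \phi m^2}
#' (Poisson when \eqn{\phi = 0}).
#'
#' @param fpkm Numeric vector of true FPKM (optionally named by gene).
#' @param params A [sim_params()] object supplying `n_reps`, `dispersion`,
#'   `libsize` and `gene_length_bp`.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return Integer matrix, genes x replicates, with replicate columns
#'   `rep1..repk`.
#' @export
simulate_counts <- function(fpkm, params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (any(!is.finite(fpkm)) || any(fpkm < 0)) stop("fpkm must be finite and >= 0")
  set.seed(seed)
  m <- fpkm * (params$gene_length_bp / 1000) * (params$libsize / 1e6)
  n <- length(m); k <- params$n_reps
  draw <- function(mm) {
    if (params$dispersion == 0) stats::rpois(length(mm), mm)
    else stats::rnbinom(length(mm), size = 1 / params$dispersion, mu = mm)
  }
  counts <- matrix(0L, n, k,
                   dimnames = list(names(fpkm), paste0("rep", seq_len(k))))
  for (j in seq_len(k)) counts[, j] <- as.integer(draw(m))
  counts
}

#' Simulate a full paired ribo-/mRNA-seq dataset over two conditions
#'
#' Builds on [simulate_pair_expression()]: condition `c1` uses the drawn
#' truth directly; in condition `c2` a planted fraction of genes has its TE
#' multiplied by `2^te_log2fc` (mRNA unchanged), providing ground truth for
#' differential-TE detection. Optionally appends unpaired singleton genes
#' whose TE never changes.
#'
#' @param params A [sim_params()] object.
#' @param n_singletons Number of extra singleton genes.
#' @param prop_diffte Fraction of paralog genes with a planted TE shift in
#'   condition c2.
#' @param te_log2fc Log2 TE fold change applied to planted genes in c2.
#' @param prop_diffte_singleton Planted differential-TE fraction among
#'   singletons; defaults to `prop_diffte`. A lower value plants the
#'   duplicate-over-singleton enrichment of translational responses.
#' @return List with `counts` (named list `ribo_c1`, `mrna_c1`, `ribo_c2`,
#'   `mrna_c2` of count matrices), `lengths`, `truth` (pair truth table),
#'   `gene_truth` (per gene: true FPKM, TE per condition, diffte flag) and
#'   `pairs` (pair table).
#' @export
simulate_te_dataset <- function(params, n_singletons = 0, prop_diffte = 0.1,
                                te_log2fc = 2,
                                prop_diffte_singleton = prop_diffte) {
  sim <- simulate_pair_expression(params)
  expr <- sim$expression
  if (n_singletons > 0) {
    set.seed(params$seed + 1L)
    smu <- stats::rnorm(n_singletons, params$mu0, params$sigma0)
    expr <- rbind(expr, data.frame(
      gene_id = sprintf("S%05d", seq_len(n_singletons)),
      pair_id = NA_character_, copy = NA_integer_,
      mrna_fpkm = 2^smu, te = params$te0, rf_fpkm = 2^smu * params$te0))
  }
  set.seed(params$seed + 2L)
  n_genes <- nrow(expr)
  p_gene <- ifelse(is.na(expr$pair_id), prop_diffte_singleton, prop_diffte)
  diffte <- stats::runif(n_genes) < p_gene
  te_c2 <- expr$te * ifelse(diffte, 2^te_log2fc, 1)
  gene_truth <- data.frame(
    gene_id = expr$gene_id, pair_id = expr$pair_id,
    mrna_fpkm = expr$mrna_fpkm,
    te_c1 = expr$te, te_c2 = te_c2,
    rf_c1 = expr$mrna_fpkm * expr$te, rf_c2 = expr$mrna_fpkm * te_c2,
    diffte = diffte, stringsAsFactors = FALSE)
  gn <- gene_truth$gene_id
  named <- function(x) stats::setNames(x, gn)
  counts <- list(
    mrna_c1 = simulate_counts(named(gene_truth$mrna_fpkm), params, params$seed + 11L),
    ribo_c1 = simulate_counts(named(gene_truth$rf_c1),   params, params$seed + 12L),
    mrna_c2 = simulate_counts(named(gene_truth$mrna_fpkm), params, params$seed + 13L),
    ribo_c2 = simulate_counts(named(gene_truth$rf_c2),   params, params$seed + 14L))
  lengths <- stats::setNames(rep(params$gene_length_bp, n_genes), gn)
  list(counts = counts, lengths = lengths, truth = sim$truth,
       gene_truth = gene_truth,
       pairs = sim$truth[, c("pair_id", "gene1", "gene2")])
}
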