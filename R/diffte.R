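#' Method-of-moments negative-binomial dispersion per gene
#'
#' Pools the moment relation `Var = m + phi m^2` across all
#' assay-by-condition groups with at least two replicates:
#' \deqn{\hat\phi_g = \frac{\sum_j (n_j - 1)(s_j^2 - \bar m_j)}
#'   {\sum_j (n_j - 1) \bar m_j^2}}
#' (for a single group this is the plain `(s^2 - m)/m^2` estimator). With
#' few replicates the gene-wise estimate is noisy and underestimates would
#' make the interaction LRT anti-conservative, so each gene's dispersion is
#' floored at the larger of `phi_floor` and the cohort-wide median of the
#' raw gene-wise estimates (`cohort_floor = TRUE`; a no-op for a
#' single-gene cohort). Genes with zero counts everywhere get `NA` and are
#' excluded from testing.
#'
#' @param counts Matrix, genes x samples.
#' @param groups Factor/character of length `ncol(counts)` giving the
#'   assay-by-condition group of each sample.
#' @param phi_floor Lower bound on the dispersion (default 0.01).
#' @param cohort_floor Also floor at the cohort median raw estimate
#'   (default TRUE).
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, groups, phi_floor = 0.01,
                                cohort_floor = TRUE) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (all(sizes < 2))
    stop("dispersion estimation needs >= 2 replicates in at least one group")
  use <- names(sizes)[sizes >= 2]
  raw <- vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    if (all(x == 0)) return(NA_real_)
    num <- 0; den <- 0
    for (g in use) {
      xi <- x[groups == g]; m <- mean(xi); k <- length(xi) - 1
      if (m > 0) { num <- num + k * (stats::var(xi) - m); den <- den + k * m^2 }
    }
    if (den == 0) return(NA_real_)
    num / den
  }, numeric(1))
  floor_val <- phi_floor
  if (cohort_floor && sum(!is.na(raw)) > 1)
    floor_val <- max(phi_floor, stats::median(raw, na.rm = TRUE))
  phi <- ifelse(is.na(raw), NA_real_, pmax(raw, floor_val))
  stats::setNames(phi, rownames(counts))
}

#' Negative-binomial GLM interaction test for differential TE
#'
#' Fits, per gene, a negative-binomial log-linear model of the fragment
#' counts with a log library-size offset and terms
#' `intercept + assay + condition + assay:condition` at a fixed per-gene
#' dispersion, and drops the interaction for the null fit. The interaction
#' coefficient is the log change of translational efficiency (ribo/mRNA
#' ratio) between the two conditions; its likelihood-ratio statistic is
#' referred to chi-square with one degree of freedom. Genes are flagged at
#' BH-adjusted p < `fdr`. This is a deliberately simple single-dispersion
#' GLM (no shrinkage across genes), in the spirit of RiboDiff's model.
#'
#' @param counts Matrix, genes x samples.
#' @param design Data frame with one row per sample (in column order of
#'   `counts`): `assay` ("mrna"/"ribo"), `condition` (two levels),
#'   optional `libsize` (defaults to column sums of `counts`).
#' @param phi Per-gene dispersions; estimated via [estimate_dispersion()]
#'   when NULL.
#' @param fdr FDR threshold for flagging (default 0.05).
#' @return Data frame per gene: `log2_interaction`, `stat`, `p`, `padj`,
#'   `flag`, `tested`.
#' @export
te_interaction_test <- function(counts, design, phi = NULL, fdr = 0.05) {
  stopifnot(is.matrix(counts), nrow(design) == ncol(counts),
            all(c("assay", "condition") %in% names(design)))
  assay <- factor(design$assay, levels = c("mrna", "ribo"))
  cond <- factor(design$condition)
  if (nlevels(cond) != 2 || nlevels(droplevels(assay)) != 2)
    stop("design needs both assays and exactly two conditions")
  libsize <- if ("libsize" %in% names(design)) design$libsize
             else colSums(counts)
  if (any(libsize <= 0)) stop("library sizes must be > 0")
  if (is.null(phi))
    phi <- estimate_dispersion(counts, interaction(assay, cond))
  off <- log(libsize)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0) || is.na(phi[i]))
      return(data.frame(log2_interaction = NA_real_, stat = NA_real_,
                        p = NA_real_, tested = FALSE))
    fam <- MASS::negative.binomial(theta = 1 / phi[i], link = "log")
    fit <- tryCatch({
      full <- stats::glm(y ~ assay * cond + offset(off), family = fam,
                         control = list(maxit = 100, epsilon = 1e-8))
      red <- stats::glm(y ~ assay + cond + offset(off), family = fam,
                        control = list(maxit = 100, epsilon = 1e-8))
      if (!full$converged || !red$converged) return(NULL)
      list(full = full, red = red)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit))
      return(data.frame(log2_interaction = NA_real_, stat = NA_real_,
                        p = NA_real_, tested = FALSE))
    stat <- max(0, fit$red$deviance - fit$full$deviance)
    cf <- stats::coef(fit$full)
    inter <- cf[grep(":", names(cf))][1]
    data.frame(log2_interaction = unname(inter) / log(2), stat = stat,
               p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               tested = TRUE)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene_id = rownames(counts), out)
  out$padj <- bh_fdr(out$p)
  out$flag <- !is.na(out$padj) & out$padj < fdr
  rownames(out) <- NULL
  out
}

#' Neither/either/both summary of differential TE across paralog pairs
#'
#' Counts, per duplication type, the pairs where neither, exactly one
#' ("either"), or both copies show differential TE, and tests whether
#' differential-TE genes are enriched in duplicates relative to singletons
#' with a 2x2 chi-squared test (continuity corrected).
#'
#' @param flags Data frame `gene_id`, `flag` (from [te_interaction_test()]).
#' @param pairs Data frame `gene1`, `gene2`, `dup_type`.
#' @param classes Optional data frame `gene_id`, `class` (from
#'   [classify_genes()]) enabling the duplicate-vs-singleton contrast;
#'   `unclassified` genes are excluded from it.
#' @return List: `pair_table` (per dup_type: neither/either/both counts and
#'   proportions) and `enrichment` (`table`, `p`) or NULL.
#' @export
pair_differential_summary <- function(flags, pairs, classes = NULL) {
  fl <- stats::setNames(flags$flag, flags$gene_id)
  f1 <- fl[pairs$gene1]; f2 <- fl[pairs$gene2]
  n_flagged <- ifelse(is.na(f1) | is.na(f2), NA_integer_, f1 + f2)
  cat3 <- c("neither", "either", "both")[n_flagged + 1L]
  dt <- if ("dup_type" %in% names(pairs)) pairs$dup_type else "all"
  tab <- as.data.frame(table(dup_type = dt[!is.na(cat3)],
                             category = factor(cat3[!is.na(cat3)],
                                               levels = c("neither", "either", "both"))))
  wide <- stats::reshape(tab, idvar = "dup_type", timevar = "category",
                         direction = "wide")
  names(wide) <- sub("^Freq\\.", "n_", names(wide))
  tot <- wide$n_neither + wide$n_either + wide$n_both
  wide$prop_either <- wide$n_either / tot
  wide$prop_both <- wide$n_both / tot
  enrichment <- NULL
  if (!is.null(classes)) {
    m <- merge(classes, flags[, c("gene_id", "flag")], by = "gene_id")
    m <- m[m$class != "unclassified" & !is.na(m$flag), , drop = FALSE]
    grp <- ifelse(m$class == "singleton", "singleton", "duplicate")
    if (length(unique(grp)) == 2) {
      ct <- table(group = grp, diffte = m$flag)
      ch <- suppressWarnings(stats::chisq.test(ct, correct = TRUE))
      enrichment <- list(table = ct, p = ch$p.value,
                         prop_duplicate = mean(m$flag[grp == "duplicate"]),
                         prop_singleton = mean(m$flag[grp == "singleton"]))
    }
  }
  rownames(wide) <- NULL
  list(pair_table = wide, enrichment = enrichment)
}
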