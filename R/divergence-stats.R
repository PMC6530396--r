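#' Classify translational buffering per paralog pair
#'
#' A pair is `buffered` when its transcriptional divergence decreases at
#' the translational level, i.e. `|RD_RF| < |RD_mRNA|`; `reinforced` when
#' it increases; `tie` when equal (which happens exactly when the two
#' copies share the same TE). Pairs with a TE fold difference of at least
#' `te_fold_min` are flagged for the restricted analysis.
#'
#' @param pair_div Output of [pair_divergence_table()].
#' @param te_fold_min TE fold-difference threshold for the restricted
#'   subset (default 2).
#' @return `pair_div` with columns `call` (buffered/reinforced/tie, NA when
#'   the RDs are undefined) and `eligible_2fold`.
#' @export
classify_buffering <- function(pair_div, te_fold_min = 2) {
  stopifnot(all(c("rd_mrna", "rd_rf", "fd_te") %in% names(pair_div)))
  a_m <- abs(pair_div$rd_mrna); a_r <- abs(pair_div$rd_rf)
  call <- ifelse(is.na(a_m) | is.na(a_r), NA_character_,
          ifelse(a_r < a_m, "buffered",
          ifelse(a_r > a_m, "reinforced", "tie")))
  pair_div$call <- call
  pair_div$eligible_2fold <- !is.na(pair_div$fd_te) &
    pair_div$fd_te >= te_fold_min
  pair_div
}

#' Exact two-sided binomial test for directionality
#'
#' Tests whether `k` successes out of `n` informative pairs depart from
#' probability `p0`, with the two-sided p-value computed by the
#' minimum-likelihood method (which equals equal-tail doubling when
#' `p0 = 0.5`). Ties must be excluded from `n` by the caller.
#'
#' @param k Number of successes (e.g. buffered pairs).
#' @param n Number of informative pairs.
#' @param p0 Null success probability (default 0.5).
#' @return P-value, or `NA` when `n = 0`.
#' @export
binomial_directionality_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  if (n == 0) return(NA_real_)
  stats::binom.test(k, n, p = p0)$p.value
}

#' Pearson correlation between two divergence vectors
#'
#' @param x,y Paired numeric vectors (pairs with a missing value in either
#'   are dropped).
#' @return List with `r`, `p` (two-sided, t-distribution with n-2 df) and `n`.
#' @export
correlate_divergences <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Contrast mRNA versus TE fold differences
#'
#' Compares the per-pair fold differences of mRNA abundance and TE with a
#' paired two-sided Wilcoxon signed-rank test on
#' `log2(FD_mRNA) - log2(FD_TE)` (zero differences dropped; exact
#' distribution for <= 25 informative pairs without ties, normal
#' approximation with continuity correction otherwise), and counts pairs
#' with the larger mRNA fold difference versus the reverse, with an exact
#' binomial test against 0.5.
#'
#' @param fd_mrna,fd_te Paired fold-difference vectors (>= 1).
#' @return List: `wilcoxon_p`, `n_mrna_greater`, `n_te_greater`, `binom_p`,
#'   `n_informative`, `median_log2_fd_mrna`, `median_log2_fd_te`.
#' @export
compare_fold_differences <- function(fd_mrna, fd_te) {
  ok <- is.finite(fd_mrna) & is.finite(fd_te)
  d <- log2(fd_mrna[ok]) - log2(fd_te[ok])
  dz <- d[d != 0]
  n_up <- sum(dz > 0); n_dn <- sum(dz < 0)
  if (length(dz) == 0) {
    return(list(wilcoxon_p = NA_real_, n_mrna_greater = 0L,
                n_te_greater = 0L, binom_p = NA_real_, n_informative = 0L,
                median_log2_fd_mrna = stats::median(log2(fd_mrna[ok])),
                median_log2_fd_te = stats::median(log2(fd_te[ok]))))
  }
  use_exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
  wp <- suppressWarnings(
    stats::wilcox.test(dz, mu = 0, exact = use_exact, correct = TRUE)$p.value)
  list(wilcoxon_p = wp, n_mrna_greater = n_up, n_te_greater = n_dn,
       binom_p = binomial_directionality_test(n_up, n_up + n_dn),
       n_informative = length(dz),
       median_log2_fd_mrna = stats::median(log2(fd_mrna[ok])),
       median_log2_fd_te = stats::median(log2(fd_te[ok])))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; `NA` p-values are
#' passed through.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Summarise buffering calls
#'
#' Counts buffered and reinforced pairs (ties excluded from the binomial
#' denominator) and tests the buffered fraction against 0.5, for all
#' informative pairs and for the subset with TE fold difference >= 2.
#'
#' @param calls Output of [classify_buffering()].
#' @return Data frame with one row per subset (`all`, `te_fold_ge_2`):
#'   counts, buffered fraction and binomial p.
#' @export
buffering_summary <- function(calls) {
  one <- function(df, label) {
    k_b <- sum(df$call == "buffered", na.rm = TRUE)
    k_r <- sum(df$call == "reinforced", na.rm = TRUE)
    ties <- sum(df$call == "tie", na.rm = TRUE)
    n <- k_b + k_r
    data.frame(subset = label, n_pairs = sum(!is.na(df$call)),
               n_buffered = k_b, n_reinforced = k_r, n_ties = ties,
               buffered_fraction = if (n > 0) k_b / n else NA_real_,
               binom_p = binomial_directionality_test(k_b, n),
               stringsAsFactors = FALSE)
  }
  rbind(one(calls, "all"),
        one(calls[calls$eligible_2fold %in% TRUE, , drop = FALSE],
            "te_fold_ge_2"))
}

#' Correlate per-pair feature divergences with TE divergence
#'
#' For each sequence feature (CDS GC content, CDS length, 3' UTR length,
#' 3' UTR minimum free energy, ...), correlates the per-pair relative
#' divergence of the feature with the relative divergence of TE.
#'
#' @param feature_rd Data frame of per-pair feature relative divergences
#'   (one column per feature, rows aligned with `rd_te`).
#' @param rd_te Vector of per-pair TE relative divergence.
#' @return Data frame `feature`, `r`, `p`, `n`.
#' @export
feature_divergence_correlations <- function(feature_rd, rd_te) {
  rows <- lapply(names(feature_rd), function(f) {
    res <- tryCatch(correlate_divergences(feature_rd[[f]], rd_te),
                    error = function(e) list(r = NA_real_, p = NA_real_, n = 0L))
    data.frame(feature = f, r = res$r, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split-replicate control for the mRNA/TE divergence correlation
#'
#' The headline correlation between RD_mRNA and RD_TE shares the mRNA
#' measurement on both axes (TE = RF/mRNA), so shared measurement noise can
#' bias it negative even without true buffering. This control recomputes
#' the correlation using disjoint mRNA replicate subsets: RD_mRNA from
#' subset A and the mRNA denominator of TE from subset B, so no replicate
#' contributes noise to both axes. This is an addition beyond the headline
#' analysis, reported alongside it.
#'
#' @param pairs Pair table (`gene1`, `gene2`, optional `pair_id`).
#' @param mrna_counts,ribo_counts Count matrices, genes x replicates; the
#'   mRNA matrix needs >= 2 replicates.
#' @param lengths Named vector of effective gene lengths (bp).
#' @param fpkm_min Low-expression threshold.
#' @return List: `r`, `p`, `n`, plus the replicate indices used for each
#'   subset.
#' @export
split_replicate_control <- function(pairs, mrna_counts, ribo_counts, lengths,
                                    fpkm_min = 0.1) {
  if (ncol(mrna_counts) < 2)
    stop("split-replicate control needs >= 2 mRNA replicates")
  idx <- seq_len(ncol(mrna_counts))
  a <- idx[idx %% 2 == 1]; b <- idx[idx %% 2 == 0]
  avg <- function(counts, cols) {
    m <- counts[, cols, drop = FALSE]
    average_replicates(fpkm_from_counts(m, lengths))
  }
  mrna_a <- avg(mrna_counts, a); mrna_b <- avg(mrna_counts, b)
  ribo <- avg(ribo_counts, seq_len(ncol(ribo_counts)))
  val <- function(v, g) ifelse(g %in% names(v), unname(v[g]), NA_real_)
  g1 <- pairs$gene1; g2 <- pairs$gene2
  m1a <- val(mrna_a, g1); m2a <- val(mrna_a, g2)
  m1b <- val(mrna_b, g1); m2b <- val(mrna_b, g2)
  r1 <- val(ribo, g1); r2 <- val(ribo, g2)
  pass <- !is.na(m1a) & !is.na(m2a) & !is.na(m1b) & !is.na(m2b) &
    !is.na(r1) & !is.na(r2) &
    m1a >= fpkm_min & m2a >= fpkm_min & m1b >= fpkm_min & m2b >= fpkm_min &
    r1 >= fpkm_min & r2 >= fpkm_min
  rd_mrna <- relative_divergence(m1a[pass], m2a[pass])
  rd_te <- relative_divergence(compute_te(r1, m1b)[pass],
                               compute_te(r2, m2b)[pass])
  res <- correlate_divergences(rd_mrna, rd_te)
  c(res, list(replicates_a = a, replicates_b = b))
}
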