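## Molecular-clock likelihood-ratio test on (paralog1, paralog2, outgroup)
## triplets under the Jukes-Cantor model.

# Under JC69 on a 3-taxon star tree the site likelihood depends only on
# which leaves share a base, so the 5 site-pattern classes are sufficient:
# all equal; leaf1==leaf2 only; leaf1==leaf3 only; leaf2==leaf3 only;
# all different.
triplet_pattern_counts <- function(triplet) {
  stopifnot(inherits(triplet, "triplet_alignment"))
  seqs <- toupper(triplet$seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("triplet sequences must have equal length")
  m <- rbind(strsplit(seqs[[1]], "")[[1]],
             strsplit(seqs[[2]], "")[[1]],
             strsplit(seqs[[3]], "")[[1]])
  cod <- function(s) substring(s, seq(1, L, 3), seq(3, L, 3))
  c1 <- cod(seqs[[1]]); c2 <- cod(seqs[[2]]); c3 <- cod(seqs[[3]])
  ok_codon <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2) &
    grepl("^[ACGT]{3}$", c3) &
    !is_stop_codon(c1) & !is_stop_codon(c2) & !is_stop_codon(c3)
  keep <- rep(ok_codon, each = 3)
  m <- m[, keep, drop = FALSE]
  e12 <- m[1, ] == m[2, ]; e13 <- m[1, ] == m[3, ]; e23 <- m[2, ] == m[3, ]
  counts <- c(
    all_same = sum(e12 & e13),
    s12 = sum(e12 & !e13),
    s13 = sum(e13 & !e12),
    s23 = sum(e23 & !e12),
    all_diff = sum(!e12 & !e13 & !e23))
  list(counts = counts, n_sites = ncol(m), n_codons_used = sum(ok_codon))
}

# log-likelihood of pattern-class counts given star-tree branch lengths
jc_star_lnl <- function(b, counts) {
  p <- exp(-4 * b / 3)
  s <- (1 + 3 * p) / 4   # P(no net change) per branch
  d <- (1 - p) / 4       # P(change to one specific base)
  q <- c(
    all_same = (s[1] * s[2] * s[3] + 3 * d[1] * d[2] * d[3]) / 4,
    s12 = (s[1] * s[2] * d[3] + d[1] * d[2] * s[3] + 2 * d[1] * d[2] * d[3]) / 4,
    s13 = (s[1] * d[2] * s[3] + d[1] * s[2] * d[3] + 2 * d[1] * d[2] * d[3]) / 4,
    s23 = (d[1] * s[2] * s[3] + s[1] * d[2] * d[3] + 2 * d[1] * d[2] * d[3]) / 4,
    all_diff = (s[1] * d[2] * d[3] + d[1] * s[2] * d[3] + d[1] * d[2] * s[3] +
                  d[1] * d[2] * d[3]) / 4)
  sum(counts * log(pmax(q, 1e-300)))
}

#' Likelihood-ratio test of clock-like paralog evolution
#'
#' Fits the Jukes-Cantor model on the unrooted 3-taxon star tree to a
#' (paralog1, paralog2, outgroup) codon alignment twice: unconstrained
#' (three free branch lengths, "asymmetric evolution") and with the two
#' paralog branches constrained equal (the molecular clock). Twice the
#' log-likelihood difference `2*dlnL = 2*(lnL_noclock - lnL_clock)` is
#' compared against a chi-square distribution with one degree of freedom.
#' Branch lengths are maximised by bounded quasi-Newton (L-BFGS-B) from
#' multiple starts (0.01, 0.1, 0.5 substitutions/site); the best start
#' wins, with a relative convergence tolerance of 1e-8 on lnL.
#'
#' Codon columns with a gap, ambiguity or stop codon in any sequence are
#' excluded; triplets with fewer than `min_codons` usable columns are not
#' tested.
#'
#' @param triplet A `triplet_alignment`.
#' @param min_codons Minimum usable codon columns (default 30).
#' @return List: `lnl_clock`, `lnl_noclock`, `stat` (2*dlnL, floored at 0),
#'   `p`, branch lengths `b1`, `b2`, `b_out` (unconstrained fit),
#'   `b_clock`, `b_out_clock`, `n_codons_used`, `converged`.
#' @export
clock_lrt <- function(triplet, min_codons = 30) {
  pc <- triplet_pattern_counts(triplet)
  if (pc$n_codons_used < min_codons)
    return(list(lnl_clock = NA_real_, lnl_noclock = NA_real_,
                stat = NA_real_, p = NA_real_, b1 = NA_real_, b2 = NA_real_,
                b_out = NA_real_, b_clock = NA_real_, b_out_clock = NA_real_,
                n_codons_used = pc$n_codons_used, converged = FALSE))
  counts <- pc$counts
  fit <- function(np, fn) {
    best <- NULL
    for (s in c(0.01, 0.1, 0.5)) {
      o <- tryCatch(stats::optim(rep(s, np), fn, method = "L-BFGS-B",
                                 lower = rep(1e-9, np), upper = rep(10, np),
                                 control = list(fnscale = -1, factr = 1e2,
                                                maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value > best$value)) best <- o
    }
    best
  }
  f_nc <- function(b) jc_star_lnl(b, counts)
  f_c  <- function(b) jc_star_lnl(c(b[1], b[1], b[2]), counts)
  o_nc <- fit(3, f_nc); o_c <- fit(2, f_c)
  if (is.null(o_nc) || is.null(o_c))
    return(list(lnl_clock = NA_real_, lnl_noclock = NA_real_, stat = NA_real_,
                p = NA_real_, b1 = NA_real_, b2 = NA_real_, b_out = NA_real_,
                b_clock = NA_real_, b_out_clock = NA_real_,
                n_codons_used = pc$n_codons_used, converged = FALSE))
  stat <- max(0, 2 * (o_nc$value - o_c$value))
  list(lnl_clock = o_c$value, lnl_noclock = o_nc$value, stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b1 = o_nc$par[1], b2 = o_nc$par[2], b_out = o_nc$par[3],
       b_clock = o_c$par[1], b_out_clock = o_c$par[2],
       n_codons_used = pc$n_codons_used, converged = TRUE)
}

#' Full rate estimates for one triplet
#'
#' Pairwise Nei-Gojobori Ka/Ks for paralog1-paralog2, paralog1-outgroup and
#' paralog2-outgroup, the triplet consistency filter, the clock LRT, and
#' the signed relative divergences of Ka and Ka/Ks between the paralogs
#' (attributing each paralog's rate to its branch via the Ka to the
#' outgroup).
#'
#' @param triplet A `triplet_alignment`.
#' @param min_codons Passed to [clock_lrt()].
#' @return One-row data frame.
#' @export
rate_estimates <- function(triplet, min_codons = 30) {
  s <- triplet$seqs
  k12 <- pairwise_ka_ks(s[[1]], s[[2]])
  k1o <- pairwise_ka_ks(s[[1]], s[[3]])
  k2o <- pairwise_ka_ks(s[[2]], s[[3]])
  keep <- triplet_filter(k12$ka, k1o$ka, k2o$ka)
  lrt <- clock_lrt(triplet, min_codons)
  data.frame(
    ka_12 = k12$ka, ks_12 = k12$ks, ka_ks_12 = k12$ka_ks,
    ka_1out = k1o$ka, ka_2out = k2o$ka,
    ka_ks_1out = k1o$ka_ks, ka_ks_2out = k2o$ka_ks,
    keep = keep,
    rd_ka = relative_divergence_signed_safe(k1o$ka, k2o$ka),
    rd_ka_ks = relative_divergence_signed_safe(k1o$ka_ks, k2o$ka_ks),
    lnl_clock = lrt$lnl_clock, lnl_noclock = lrt$lnl_noclock,
    lrt_stat = lrt$stat, lrt_p = lrt$p,
    b1 = lrt$b1, b2 = lrt$b2, b_out = lrt$b_out,
    n_codons_used = lrt$n_codons_used, converged = lrt$converged,
    stringsAsFactors = FALSE)
}

relative_divergence_signed_safe <- function(x1, x2) {
  if (anyNA(c(x1, x2)) || (x1 + x2) == 0) NA_real_
  else relative_divergence(x1, x2)
}

#' Asymmetric-evolution summary against RF divergence
#'
#' For pairs flagged as evolving asymmetrically (clock LRT, BH-FDR <
#' `fdr`), calls the faster-evolving copy from the larger
#' paralog-to-outgroup Ka and asks whether the copy with the higher
#' ribosome-footprint abundance tends to be the slower-evolving one
#' (exact binomial test against 0.5). Also reports the Pearson correlation
#' between RD_RF and RD_Ka over all kept pairs, and optionally restricts
#' the contingency to pairs with at least `rf_fold_min`-fold RF difference.
#'
#' @param rates Data frame from [rate_estimates()] rows (plus `pair_id`).
#' @param pair_div Pair divergence table with `pair_id`, `rd_rf`, `fd_rf`.
#' @param fdr FDR threshold for the asymmetric flag (default 0.05).
#' @param rf_fold_min RF fold-difference restriction (default 2; set to 1
#'   to disable).
#' @return List: correlation (`r`, `p`, `n_corr`), `n_asym`,
#'   `n_higher_rf_slower`, `n_higher_rf_faster`, `binom_p`.
#' @export
asymmetry_summary <- function(rates, pair_div, fdr = 0.05, rf_fold_min = 2) {
  stopifnot("pair_id" %in% names(rates), "pair_id" %in% names(pair_div))
  m <- merge(rates, pair_div[, c("pair_id", "rd_rf", "fd_rf")], by = "pair_id")
  m <- m[m$keep %in% TRUE & !is.na(m$rd_rf), , drop = FALSE]
  m$lrt_padj <- bh_fdr(m$lrt_p)
  corr <- if (sum(!is.na(m$rd_ka)) >= 3)
    correlate_divergences(m$rd_rf, m$rd_ka)
  else list(r = NA_real_, p = NA_real_, n = 0L)
  sub <- m[!is.na(m$lrt_padj) & m$lrt_padj < fdr &
             !is.na(m$fd_rf) & m$fd_rf >= rf_fold_min &
             !is.na(m$ka_1out) & !is.na(m$ka_2out) &
             m$ka_1out != m$ka_2out, , drop = FALSE]
  faster_is_2 <- sub$ka_2out > sub$ka_1out
  higher_rf_is_2 <- sub$rd_rf > 0
  # higher-RF copy is the slower-evolving one when the two labels disagree
  n_slower <- sum(faster_is_2 != higher_rf_is_2)
  n_faster <- sum(faster_is_2 == higher_rf_is_2)
  list(r = corr$r, p = corr$p, n_corr = corr$n,
       n_asym = nrow(sub),
       n_higher_rf_slower = n_slower,
       n_higher_rf_faster = n_faster,
       binom_p = binomial_directionality_test(n_slower, n_slower + n_faster))
}
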