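# Independent oracles used to cross-check the package implementations.
# Each is written directly from the mathematical definition, not by calling
# the functions under test.

# two-sided exact binomial p by minimum-likelihood enumeration over the PMF
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  raw <- p[ord] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(raw))), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

ORACLE_GC <- Biostrings::GENETIC_CODE

# synonymous site count of one codon: per position, fraction of
# non-stop-producing single-base changes that preserve the amino acid
oracle_codon_syn_sites <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), nts[pos]), function(a) {
      x <- nts; x[pos] <- a; paste(x, collapse = "")
    }, character(1))
    keep <- muts[ORACLE_GC[muts] != "*"]
    if (length(keep))
      total <- total + sum(ORACLE_GC[keep] == ORACLE_GC[codon]) / length(keep)
  }
  total
}

# all permutations of a vector (tiny n)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# exhaustive minimal-pathway enumeration between two codons
oracle_codon_diffs <- function(c1, c2) {
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  if (!length(pos)) return(c(nd = 0, sd = 0))
  score <- function(order, allow_stop) {
    cur <- n1; nd <- 0; sd <- 0
    for (p in order) {
      from <- paste(cur, collapse = "")
      cur[p] <- n2[p]
      to <- paste(cur, collapse = "")
      if (!allow_stop && ORACLE_GC[[to]] == "*") return(NULL)
      if (ORACLE_GC[[from]] == ORACLE_GC[[to]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(nd = nd, sd = sd)
  }
  perms <- oracle_perms(pos)
  res <- Filter(Negate(is.null), lapply(perms, score, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, score, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

oracle_sense_codons <- names(ORACLE_GC)[ORACLE_GC != "*"]

# buffering by direct log-ratio comparison
oracle_buffering_call <- function(m1, m2, r1, r2) {
  a_m <- abs(log2(m2 / m1)); a_r <- abs(log2(r2 / r1))
  ifelse(a_r < a_m, "buffered", ifelse(a_r > a_m, "reinforced", "tie"))
}

# noise-free pair-divergence table straight from a truth table
truth_pair_div <- function(truth) {
  data.frame(
    pair_id = truth$pair_id,
    rd_mrna = (truth$mrna2 - truth$mrna1) / (truth$mrna1 + truth$mrna2),
    rd_rf = (truth$rf2 - truth$rf1) / (truth$rf1 + truth$rf2),
    rd_te = (truth$te2 - truth$te1) / (truth$te1 + truth$te2),
    fd_te = pmax(truth$te1, truth$te2) / pmin(truth$te1, truth$te2),
    fd_mrna = pmax(truth$mrna1, truth$mrna2) / pmin(truth$mrna1, truth$mrna2),
    stringsAsFactors = FALSE)
}
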