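## Nei-Gojobori (1986) style counting of synonymous and non-synonymous
## sites and differences, with Jukes-Cantor multiple-hit correction.

# Per-codon synonymous site count: at each position, the fraction of the
# possible single-nucleotide changes that are synonymous; mutations creating
# a stop codon are disregarded (not counted in numerator or denominator).
# Cached for the 61 sense codons at first use.
codon_syn_sites <- function() {
  if (!is.null(.dupribo$syn_sites)) return(.dupribo$syn_sites)
  gc <- Biostrings::GENETIC_CODE
  sense <- sense_codons()
  s <- vapply(sense, function(cod) {
    nts <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) for (alt in setdiff(nuc_alphabet, nts[pos])) {
      mut <- nts; mut[pos] <- alt
      mcod <- paste(mut, collapse = "")
      if (gc[[mcod]] == "*") next
      n_ok <- sum(vapply(setdiff(nuc_alphabet, nts[pos]), function(a) {
        m2 <- nts; m2[pos] <- a; gc[[paste(m2, collapse = "")]] != "*"
      }, logical(1)))
      if (gc[[mcod]] == gc[[cod]]) tot <- tot + 1 / n_ok
    }
    tot
  }, numeric(1))
  .dupribo$syn_sites <- s
  s
}

# Synonymous/non-synonymous differences between two codons, averaged over
# all minimal mutational pathways that avoid stop codons (all pathways if
# every one is blocked).
codon_path_differences <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(nd = 0, sd = 0))
  perms <- if (k == 1) list(pos) else {
    idx <- if (k == 2) list(1:2, 2:1)
           else list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(o) pos[o])
  }
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  walk <- function(order) {
    cur <- n1; nd <- 0; sd <- 0
    for (p in order) {
      prev_cod <- paste(cur, collapse = "")
      cur[p] <- n2[p]
      next_cod <- paste(cur, collapse = "")
      if (gc[[next_cod]] == "*" && next_cod != c2) return(NULL)
      if (gc[[prev_cod]] == gc[[next_cod]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(nd = nd, sd = sd)
  }
  res <- lapply(perms, walk)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (length(ok) == 0) ok <- lapply(perms, function(o) {
    cur <- n1; nd <- 0; sd <- 0
    for (p in o) {
      prev_cod <- paste(cur, collapse = ""); cur[p] <- n2[p]
      if (gc[[prev_cod]] == gc[[paste(cur, collapse = "")]]) sd <- sd + 1
      else nd <- nd + 1
    }
    c(nd = nd, sd = sd)
  })
  Reduce(`+`, ok) / length(ok)
}

#' Count synonymous/non-synonymous sites and differences
#'
#' Nei-Gojobori style counting over a pairwise codon alignment. Codon
#' columns containing a gap, an ambiguous base or a stop codon in either
#' sequence are excluded wholly. Site counts are averaged over the two
#' sequences; multi-nucleotide codon differences are resolved by averaging
#' over all minimal mutational pathways, excluding pathways that pass
#' through a stop codon.
#'
#' @param seq1,seq2 Aligned coding sequences (equal length, multiple of 3).
#' @return List `N`, `S` (non-synonymous and synonymous sites), `Nd`, `Sd`
#'   (differences) and `n_codons_used`.
#' @export
count_sites_and_differences <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned")
  if (nchar(seq1) %% 3 != 0) stop("alignment length must be a multiple of 3")
  cod1 <- substring(seq1, seq(1, nchar(seq1), 3), seq(3, nchar(seq1), 3))
  cod2 <- substring(seq2, seq(1, nchar(seq2), 3), seq(3, nchar(seq2), 3))
  clean <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2) &
    !is_stop_codon(cod1) & !is_stop_codon(cod2)
  cod1 <- cod1[clean]; cod2 <- cod2[clean]
  ss <- codon_syn_sites()
  S <- (sum(ss[cod1]) + sum(ss[cod2])) / 2
  N <- 3 * length(cod1) - S
  nd <- 0; sd <- 0
  diff <- which(cod1 != cod2)
  for (i in diff) {
    d <- codon_path_differences(cod1[i], cod2[i])
    nd <- nd + d[["nd"]]; sd <- sd + d[["sd"]]
  }
  list(N = N, S = S, Nd = nd, Sd = sd, n_codons_used = length(cod1))
}

#' Ka and Ks with Jukes-Cantor correction
#'
#' `Ka = -(3/4) ln(1 - (4/3) pn)` with `pn = Nd/N`, likewise `Ks`.
#' Proportions of 3/4 or more are saturated and yield `NA`. `Ka/Ks` is `NA`
#' when `Ks = 0` (including the 0/0 case of identical sequences).
#'
#' @param N,S,Nd,Sd Site and difference counts from
#'   [count_sites_and_differences()].
#' @return List `ka`, `ks`, `ka_ks`, `saturated`.
#' @export
ka_ks <- function(N, S, Nd, Sd) {
  if (N <= 0 || S <= 0) stop("N and S must be > 0")
  pn <- Nd / N; ps <- Sd / S
  sat <- pn >= 0.75 || ps >= 0.75
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  ka <- if (pn >= 0.75) NA_real_ else jc(pn)
  ks <- if (ps >= 0.75) NA_real_ else jc(ps)
  list(ka = ka, ks = ks,
       ka_ks = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
       saturated = sat)
}

#' Pairwise Ka/Ks from a codon alignment
#'
#' @param seq1,seq2 Aligned coding sequences.
#' @return As [ka_ks()], plus the underlying counts.
#' @export
pairwise_ka_ks <- function(seq1, seq2) {
  cnt <- count_sites_and_differences(seq1, seq2)
  c(ka_ks(cnt$N, cnt$S, cnt$Nd, cnt$Sd), cnt)
}

#' Triplet consistency filter
#'
#' Discards a triplet when the Ka between the two paralogs is strictly
#' larger than the Ka between either paralog and the outgroup ortholog — a
#' sign that the outgroup does not predate the duplication, making branch
#' attribution unreliable. Undefined Ka also discards.
#'
#' @param ka_12,ka_1out,ka_2out Pairwise Ka estimates.
#' @return TRUE to keep, FALSE to discard.
#' @export
triplet_filter <- function(ka_12, ka_1out, ka_2out) {
  if (anyNA(c(ka_12, ka_1out, ka_2out))) return(FALSE)
  !(ka_12 > min(ka_1out, ka_2out))
}
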