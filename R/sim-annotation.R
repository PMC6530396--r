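#' Simulate a gene annotation with planted tandem clusters
#'
#' Generates a background annotation (evenly spaced genes with unique family
#' ids, so none of them cluster) and plants gene clusters with controlled
#' geometry: each planted cluster specifies its family id, member count, the
#' number of intervening genes between adjacent members, the start-to-start
#' span between adjacent members, and whether the members share a
#' chromosome. The returned truth record states, per cluster, whether the
#' planted geometry satisfies the tandem eligibility rules (same family,
#' at most 10 intervening genes, within 100 kb on the same chromosome).
#'
#' For clusters with more than two members the `intervening` and `span_bp`
#' values apply between each adjacent member pair.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_genes Number of background genes (split across chromosomes).
#' @param planted_clusters A data frame (or list coercible to one) with
#'   columns `family_id`, `n_members`, `intervening`, `span_bp` and
#'   optionally `same_chrom` (default TRUE).
#' @param spacing_bp Start-to-start spacing of background genes.
#' @param seed RNG seed (strands are drawn at random).
#' @param max_intervening,max_span_bp Rule thresholds recorded in the truth.
#' @return List with `annotation` (data frame: gene_id, chrom, start, end,
#'   strand, family_id) and `truth` (per planted cluster: member ids and
#'   `tandem_eligible`).
#' @export
simulate_gene_annotation <- function(n_chrom = 2, n_genes = 100,
                                     planted_clusters = NULL,
                                     spacing_bp = 10000, seed = 1L,
                                     max_intervening = 10,
                                     max_span_bp = 100000) {
  stopifnot(n_chrom >= 1, n_genes >= 0, spacing_bp > 0)
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  per_chrom <- ceiling(n_genes / n_chrom)
  ann <- list(); gi <- 0L
  for (ch in chroms) {
    k <- min(per_chrom, n_genes - gi)
    if (k <= 0) break
    starts <- spacing_bp * seq_len(k)
    ann[[ch]] <- data.frame(
      gene_id = sprintf("BG%05d", gi + seq_len(k)), chrom = ch,
      start = starts, end = starts + 999L,
      strand = sample(c("+", "-"), k, replace = TRUE),
      family_id = sprintf("FBG%05d", gi + seq_len(k)),
      stringsAsFactors = FALSE)
    gi <- gi + k
  }
  ann <- do.call(rbind, ann)
  truth <- NULL
  if (!is.null(planted_clusters)) {
    pc <- as.data.frame(planted_clusters, stringsAsFactors = FALSE)
    if (is.null(pc$same_chrom)) pc$same_chrom <- TRUE
    if (is.null(pc$n_members)) pc$n_members <- 2L
    # planted material lives beyond the background block of every chromosome
    base <- spacing_bp * (per_chrom + 2)
    region_w <- max(pc$span_bp) * max(pc$n_members) + 4 * spacing_bp
    rows <- list(); trows <- list()
    for (i in seq_len(nrow(pc))) {
      k_int <- pc$intervening[i]; span <- pc$span_bp[i]
      m <- pc$n_members[i]
      if (m < 2) stop("planted clusters need at least 2 members")
      if (k_int > 0 && span < (k_int + 1) * 2)
        stop(sprintf("cluster %s: span_bp=%d cannot host %d intervening genes",
                     pc$family_id[i], span, k_int))
      ch1 <- chroms[((i - 1) %% n_chrom) + 1]
      ch2 <- if (pc$same_chrom[i]) ch1 else chroms[(i %% n_chrom) + 1]
      if (!pc$same_chrom[i] && n_chrom < 2)
        stop("same_chrom = FALSE requires n_chrom >= 2")
      start0 <- base + (i - 1) * region_w
      member_starts <- start0 + span * (0:(m - 1))
      member_chrom <- c(ch1, rep(ch2, m - 1))
      gw <- max(1, min(500, floor(span / (k_int + 1)) - 2))
      mem <- data.frame(
        gene_id = sprintf("%s_m%d", pc$family_id[i], seq_len(m)),
        chrom = member_chrom, start = member_starts,
        end = member_starts + gw,
        strand = "+", family_id = pc$family_id[i], stringsAsFactors = FALSE)
      fill <- NULL
      if (k_int > 0) {
        fs <- unlist(lapply(seq_len(m - 1), function(j)
          member_starts[j] + round(span * seq_len(k_int) / (k_int + 1))))
        fill <- data.frame(
          gene_id = sprintf("%s_f%d", pc$family_id[i], seq_along(fs)),
          chrom = rep(member_chrom[-1], each = k_int), start = fs,
          end = fs + max(1, gw - 1), strand = "-",
          family_id = sprintf("%s_f%d", pc$family_id[i], seq_along(fs)),
          stringsAsFactors = FALSE)
      }
      rows[[i]] <- rbind(mem, fill)
      eligible <- pc$same_chrom[i] && k_int <= max_intervening &&
        span <= max_span_bp
      trows[[i]] <- data.frame(
        family_id = pc$family_id[i], n_members = m,
        intervening = k_int, span_bp = span, same_chrom = pc$same_chrom[i],
        members = paste(mem$gene_id, collapse = ","),
        tandem_eligible = eligible, stringsAsFactors = FALSE)
    }
    ann <- rbind(ann, do.call(rbind, rows))
    truth <- do.call(rbind, trows)
  }
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), ]
  rownames(ann) <- NULL
  list(annotation = ann, truth = truth)
}
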