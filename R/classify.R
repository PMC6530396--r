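#' Select the longest isoform per gene
#'
#' For genes with multiple isoforms only the one with the longest sequence
#' is kept as the representative gene model. Length is taken from a
#' `cds_length` column when present, otherwise from `nchar(cds_sequence)`.
#' Ties are broken by the lexicographically smallest `isoform_id` so the
#' choice is deterministic.
#'
#' @param models Data frame with columns `gene_id`, `isoform_id` and either
#'   `cds_length` or `cds_sequence` (other columns are carried through).
#' @return Data frame with one row per gene.
#' @export
select_representative_isoform <- function(models) {
  stopifnot(is.data.frame(models), all(c("gene_id", "isoform_id") %in% names(models)))
  len <- if ("cds_length" %in% names(models)) models$cds_length
         else if ("cds_sequence" %in% names(models)) nchar(models$cds_sequence)
         else stop("models need a cds_length or cds_sequence column")
  if (anyNA(len)) stop("every isoform needs a sequence or a length")
  ord <- order(models$gene_id, -len, models$isoform_id)
  m <- models[ord, , drop = FALSE]
  out <- m[!duplicated(m$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster tandem duplicates
#'
#' Two genes join a tandem cluster when they (i) belong to the same gene
#' family, (ii) are separated by at most `max_intervening` annotated genes,
#' and (iii) lie within `max_span_bp` on the same chromosome; both bounds
#' are inclusive. Clusters are maximal under single-linkage chaining of this
#' pairwise relation, so a cluster may span more than `max_span_bp` end to
#' end as long as each consecutive link qualifies. The intervening count is
#' the number of representative gene models whose start lies strictly
#' between the two members' starts; the distance is `|start2 - start1|`.
#'
#' @param annotation Data frame with `gene_id`, `chrom`, `start`,
#'   `family_id` (one representative model per gene).
#' @param max_intervening Maximum number of genes between cluster neighbours.
#' @param max_span_bp Maximum start-to-start distance in bp.
#' @return Data frame `gene_id`, `family_id`, `chrom`, `cluster_id`,
#'   `cluster_size`, covering every gene with a family id (singleton
#'   clusters included).
#' @export
cluster_tandem <- function(annotation, max_intervening = 10,
                           max_span_bp = 100000) {
  stopifnot(all(c("gene_id", "chrom", "start", "family_id") %in% names(annotation)))
  ann <- annotation
  no_fam <- is.na(ann$family_id) | ann$family_id == ""
  if (any(no_fam)) {
    warning(sum(no_fam), " gene(s) without family_id excluded from tandem clustering")
    ann <- ann[!no_fam, , drop = FALSE]
  }
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  res <- list(); cl <- 0L
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, , drop = FALSE]
    starts_all <- sort(sub$start)
    for (fam in unique(sub$family_id)) {
      mem <- sub[sub$family_id == fam, , drop = FALSE]
      n <- nrow(mem)
      # chain consecutive same-family genes; eligibility is monotone in
      # genomic order, so consecutive links realise single linkage exactly
      grp <- integer(n); grp[1] <- 1L
      if (n > 1) for (i in 2:n) {
        s1 <- mem$start[i - 1]; s2 <- mem$start[i]
        n_between <- sum(starts_all > s1 & starts_all < s2)
        ok <- n_between <= max_intervening && (s2 - s1) <= max_span_bp
        grp[i] <- if (ok) grp[i - 1] else grp[i - 1] + 1L
      }
      for (g in unique(grp)) {
        cl <- cl + 1L
        idx <- grp == g
        res[[cl]] <- data.frame(
          gene_id = mem$gene_id[idx], family_id = fam, chrom = ch,
          cluster_id = sprintf("TC%05d", cl), cluster_size = sum(idx),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$cluster_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick representative duplicate pairs from tandem clusters
#'
#' Clusters of two return their members; for larger clusters two genes are
#' chosen uniformly at random as the cluster's representative duplicate
#' pair, deterministically for a given seed. Size-one clusters yield no
#' pair. Pair members are reported with `gene1` the lexicographically
#' smaller id.
#'
#' @param clusters Output of [cluster_tandem()].
#' @param seed RNG seed.
#' @return Data frame `gene1`, `gene2`, `dup_type = "tandem"`,
#'   `source = "clustered"`, `cluster_id`.
#' @export
choose_cluster_representatives <- function(clusters, seed = 1L) {
  stopifnot(all(c("gene_id", "cluster_id") %in% names(clusters)))
  set.seed(seed)
  ids <- sort(unique(clusters$cluster_id))
  rows <- lapply(ids, function(cid) {
    g <- sort(clusters$gene_id[clusters$cluster_id == cid])
    if (length(g) < 2) return(NULL)
    pick <- if (length(g) == 2) g else sort(sample(g, 2))
    data.frame(gene1 = pick[1], gene2 = pick[2], dup_type = "tandem",
               source = "clustered", cluster_id = cid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene1 = character(), gene2 = character(),
                      dup_type = character(), source = character(),
                      cluster_id = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify genes into duplicate classes and singletons
#'
#' Labels follow the precedence wgd > tandem > other > singleton.
#' Genes on a curated whole-genome-duplication pair list are `wgd`; genes in
#' a tandem pair are `tandem`; remaining genes are `other` duplicates when
#' their best non-self protein hit has E-value at most `dup_e` (1e-10), and
#' `singleton` when they have no non-self hit with E-value at most
#' `single_e` (1e-3). Genes whose best hit falls between the two thresholds
#' fit neither printed rule and are reported as `unclassified`; they are
#' excluded from duplicate-versus-singleton contrasts.
#'
#' @param gene_ids Character vector: the gene universe.
#' @param hits Data frame of protein hits with columns `query_id`,
#'   `subject_id`, `e_value`; self-hits are ignored. A gene absent from the
#'   table has no hits.
#' @param wgd_pairs,tandem_pairs Data frames with `gene1`, `gene2` columns
#'   (either may be NULL or empty).
#' @param dup_e,single_e E-value thresholds for `other` and `singleton`.
#' @return Data frame `gene_id`, `class`, `best_evalue`.
#' @export
classify_genes <- function(gene_ids, hits = NULL, wgd_pairs = NULL,
                           tandem_pairs = NULL, dup_e = 1e-10,
                           single_e = 1e-3) {
  gene_ids <- unique(as.character(gene_ids))
  best <- stats::setNames(rep(Inf, length(gene_ids)), gene_ids)
  if (!is.null(hits) && nrow(hits)) {
    stopifnot(all(c("query_id", "subject_id", "e_value") %in% names(hits)))
    if (any(hits$e_value < 0)) stop("e_value must be >= 0")
    h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
    for (side in c("query_id", "subject_id")) {
      agg <- tapply(h$e_value, h[[side]], min)
      keep <- intersect(names(agg), gene_ids)
      best[keep] <- pmin(best[keep], agg[keep])
    }
  }
  in_pairs <- function(p) if (is.null(p) || !nrow(p)) character(0)
                          else unique(c(p$gene1, p$gene2))
  wgd_set <- in_pairs(wgd_pairs); tan_set <- in_pairs(tandem_pairs)
  cls <- ifelse(gene_ids %in% wgd_set, "wgd",
         ifelse(gene_ids %in% tan_set, "tandem",
         ifelse(best <= dup_e, "other",
         ifelse(best > single_e, "singleton", "unclassified"))))
  data.frame(gene_id = gene_ids, class = cls,
             best_evalue = ifelse(is.infinite(best), NA_real_, unname(best)),
             stringsAsFactors = FALSE)
}

#' Sequence features relevant to translational efficiency
#'
#' Computes per gene the CDS GC fraction (ambiguous `N` bases are excluded
#' from numerator and denominator), CDS length, 3' UTR length, and passes
#' through a precomputed minimum-free-energy value for the 3' UTR secondary
#' structure when supplied. A CDS with no unambiguous base yields `NA` GC.
#'
#' @param genes Data frame with `gene_id`, `cds_sequence` and optionally
#'   `utr3_sequence`, `mfe_3utr`.
#' @return Data frame `gene_id`, `gc_cds`, `cds_length`, `utr3_length`,
#'   `mfe_3utr`.
#' @export
compute_sequence_features <- function(genes) {
  stopifnot(all(c("gene_id", "cds_sequence") %in% names(genes)))
  seqs <- toupper(genes$cds_sequence)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("cds_sequence must be over the alphabet {A,C,G,T,N}")
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(ifelse(nchar(seqs) > 0, seqs, "N")),
    letters = c("A", "C", "G", "T"))
  unambig <- rowSums(freq)
  gc <- ifelse(unambig > 0, (freq[, "G"] + freq[, "C"]) / unambig, NA_real_)
  data.frame(
    gene_id = genes$gene_id,
    gc_cds = gc,
    cds_length = nchar(seqs),
    utr3_length = if ("utr3_sequence" %in% names(genes))
      nchar(genes$utr3_sequence) else NA_integer_,
    mfe_3utr = if ("mfe_3utr" %in% names(genes)) genes$mfe_3utr else NA_real_,
    stringsAsFactors = FALSE)
}
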