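#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / (length/1000) / (total/1e6)`.
#'
#' @param count Fragment count (vector or matrix).
#' @param gene_length_bp Effective gene length(s) in bp, > 0.
#' @param total_mapped_fragments Library total(s), > 0; for a count matrix,
#'   one total per column.
#' @return FPKM on the same shape as `count`.
#' @export
compute_fpkm <- function(count, gene_length_bp, total_mapped_fragments) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(total_mapped_fragments <= 0)) stop("total_mapped_fragments must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  if (is.matrix(count)) {
    sweep(count / (gene_length_bp / 1000), 2, total_mapped_fragments / 1e6, "/")
  } else {
    count / (gene_length_bp / 1000) / (total_mapped_fragments / 1e6)
  }
}

#' FPKM matrix from a count matrix
#'
#' Library totals default to the per-replicate sum of counted fragments
#' over all genes, the same basis used for library-size offsets in the
#' differential-TE model.
#'
#' @param counts Integer matrix, genes x replicates, with gene rownames.
#' @param lengths Named numeric vector of effective lengths (bp).
#' @param totals Per-column library totals; defaults to `colSums(counts)`.
#' @return FPKM matrix.
#' @export
fpkm_from_counts <- function(counts, lengths, totals = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!all(rownames(counts) %in% names(lengths)))
    stop("missing gene length for: ",
         paste(utils::head(setdiff(rownames(counts), names(lengths))), collapse = ", "))
  compute_fpkm(counts, lengths[rownames(counts)], totals)
}

#' Average FPKM over replicates
#'
#' @param fpkm FPKM matrix, genes x replicates (>= 1 column).
#' @return Named vector of per-gene mean FPKM.
#' @export
average_replicates <- function(fpkm) {
  stopifnot(is.matrix(fpkm), ncol(fpkm) >= 1)
  rowMeans(fpkm)
}

#' Low-expression filter
#'
#' A gene passes in a given assay and condition iff its replicate-averaged
#' FPKM is at least `threshold`; genes with average FPKM lower than the
#' threshold are filtered out, so the boundary value itself passes.
#'
#' @param avg_fpkm Named vector of averaged FPKM.
#' @param threshold Minimum average FPKM (default 0.1).
#' @return Logical vector (named like `avg_fpkm`): TRUE = kept.
#' @export
filter_low_expression <- function(avg_fpkm, threshold = 0.1) {
  avg_fpkm >= threshold
}

#' Translational efficiency
#'
#' `TE = ribo-seq FPKM / mRNA-seq FPKM`. Zero mRNA FPKM yields `NA` (such
#' genes cannot pass the expression filter).
#'
#' @param ribo_fpkm,mrna_fpkm Averaged FPKM values.
#' @return TE values.
#' @export
compute_te <- function(ribo_fpkm, mrna_fpkm) {
  ifelse(mrna_fpkm > 0, ribo_fpkm / mrna_fpkm, NA_real_)
}

#' Signed relative divergence
#'
#' `RD = (x2 - x1) / (x1 + x2)`, bounded in \[-1, 1\], antisymmetric under
#' swapping the pair, and strictly increasing in the ratio `x2/x1`.
#' Undefined (NA) when `x1 + x2 = 0`.
#'
#' @param x1,x2 Non-negative values for the first and second gene of a pair.
#' @return Relative divergence values.
#' @export
relative_divergence <- function(x1, x2) {
  if (any(c(x1, x2) < 0, na.rm = TRUE)) stop("values must be >= 0")
  s <- x1 + x2
  ifelse(is.na(s) | s == 0, NA_real_, (x2 - x1) / s)
}

#' Fold difference
#'
#' `FD = max(x1, x2) / min(x1, x2) >= 1`, symmetric in the pair. A zero
#' value gives an infinite fold difference. FD relates to the absolute
#' relative divergence by `FD = (1 + |RD|) / (1 - |RD|)`.
#'
#' @param x1,x2 Positive values.
#' @return Fold differences.
#' @export
fold_difference <- function(x1, x2) {
  if (any(c(x1, x2) < 0, na.rm = TRUE)) stop("values must be >= 0")
  pmax(x1, x2) / pmin(x1, x2)
}

#' Per-pair divergence table for one condition
#'
#' Combines averaged FPKM from both assays into the per-pair statistics:
#' signed relative divergences of mRNA abundance, RF abundance and TE, the
#' corresponding fold differences, and per-copy TE. A pair contributes only
#' if both members pass the low-expression filter in both assays
#' (`pass = TRUE`); statistics of non-passing pairs are `NA`.
#'
#' @param pairs Data frame with `pair_id` (optional), `gene1`, `gene2`.
#' @param mrna_avg,ribo_avg Named vectors of replicate-averaged FPKM.
#' @param fpkm_min Low-expression threshold (default 0.1).
#' @return Data frame, one row per pair: FPKM and TE per copy, `rd_mrna`,
#'   `rd_rf`, `rd_te`, `fd_mrna`, `fd_rf`, `fd_te`, `pass`.
#' @export
pair_divergence_table <- function(pairs, mrna_avg, ribo_avg, fpkm_min = 0.1) {
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)))
  g1 <- pairs$gene1; g2 <- pairs$gene2
  val <- function(v, g) ifelse(g %in% names(v), unname(v[g]), NA_real_)
  m1 <- val(mrna_avg, g1); m2 <- val(mrna_avg, g2)
  r1 <- val(ribo_avg, g1); r2 <- val(ribo_avg, g2)
  pass <- !is.na(m1) & !is.na(m2) & !is.na(r1) & !is.na(r2) &
    filter_low_expression(m1, fpkm_min) & filter_low_expression(m2, fpkm_min) &
    filter_low_expression(r1, fpkm_min) & filter_low_expression(r2, fpkm_min)
  te1 <- compute_te(r1, m1); te2 <- compute_te(r2, m2)
  out <- data.frame(
    pair_id = if ("pair_id" %in% names(pairs)) pairs$pair_id
              else paste(g1, g2, sep = "|"),
    gene1 = g1, gene2 = g2,
    mrna1 = m1, mrna2 = m2, rf1 = r1, rf2 = r2, te1 = te1, te2 = te2,
    rd_mrna = relative_divergence(m1, m2),
    rd_rf = relative_divergence(r1, r2),
    rd_te = relative_divergence(te1, te2),
    fd_mrna = fold_difference(m1, m2),
    fd_rf = fold_difference(r1, r2),
    fd_te = fold_difference(te1, te2),
    pass = pass, stringsAsFactors = FALSE)
  stat_cols <- c("te1", "te2", "rd_mrna", "rd_rf", "rd_te",
                 "fd_mrna", "fd_rf", "fd_te")
  out[!out$pass, stat_cols] <- NA_real_
  out
}
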