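## Readers and writers for the pipeline's plain-text formats: BED-like TSV
## and GFF3 annotations, BLAST tabular hits, pair lists, count and length
## TSVs, and the JSON run report.

#' Read a gene annotation
#'
#' Accepts a BED-like/plain TSV (columns `gene_id`, `chrom`, `start`,
#' `end`, `strand`, `family_id`; header required), a BED file (0-based
#' half-open, converted to 1-based inclusive; family id taken from column
#' 7 when present) or GFF3 (`gene` features; `family_id` read from the
#' attributes). Coordinates are 1-based inclusive internally.
#'
#' @param path Input file.
#' @param format "auto" (by extension), "tsv", "bed" or "gff3".
#' @return Annotation data frame.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    fam <- if ("family_id" %in% names(GenomicRanges::mcols(gr)))
      gr$family_id else NA_character_
    id <- if ("ID" %in% names(GenomicRanges::mcols(gr))) gr$ID else gr$Name
    return(data.frame(
      gene_id = as.character(id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      family_id = as.character(fam), stringsAsFactors = FALSE))
  }
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    out <- data.frame(gene_id = df[[4]], chrom = df[[1]],
                      start = df[[2]] + 1L, end = df[[3]],
                      strand = if (ncol(df) >= 6) df[[6]] else "*",
                      family_id = if (ncol(df) >= 7) df[[7]] else NA_character_,
                      stringsAsFactors = FALSE)
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$strand)) df$strand <- "*"
  if (is.null(df$family_id)) df$family_id <- NA_character_
  df
}

#' Write an annotation as TSV or GFF3
#' @param annotation Annotation data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "*"))
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  gr$family_id <- annotation$family_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Either the full 12-column format (E-value in column 11) or a minimal
#' 3-column `query, subject, e_value` table.
#'
#' @param path Input file.
#' @return Data frame `query_id`, `subject_id`, `e_value`.
#' @export
read_blast_hits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  ecol <- if (ncol(df) >= 11) 11 else 3
  data.frame(query_id = as.character(df[[1]]),
             subject_id = as.character(df[[2]]),
             e_value = as.numeric(df[[ecol]]), stringsAsFactors = FALSE)
}

#' Read a curated duplicate-pair list
#'
#' TSV whose first two columns are the paired gene ids; a header line is
#' detected and skipped if its first field is `gene1`.
#'
#' @param path Input file.
#' @param dup_type Duplication type to record (default "wgd").
#' @return Data frame `gene1`, `gene2`, `dup_type`, `source = "curated"`.
#' @export
read_pair_list <- function(path, dup_type = "wgd") {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]][1]
  df <- utils::read.table(path, sep = "\t", header = identical(first, "gene1"),
                          stringsAsFactors = FALSE)
  data.frame(gene1 = as.character(df[[1]]), gene2 = as.character(df[[2]]),
             dup_type = dup_type, source = "curated", stringsAsFactors = FALSE)
}

#' Read / write a count matrix TSV (genes x replicates)
#' @param path File path.
#' @return `read_count_tsv`: integer matrix with gene rownames.
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_count_tsv
#' @param counts Count matrix.
#' @export
write_count_tsv <- function(counts, path) {
  utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length TSV (`gene_id`, `length_bp`)
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_lengths_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the machine-readable run report
#'
#' Deterministic, pretty-printed JSON (no rounding) so identical runs
#' produce byte-identical reports.
#'
#' @param report Named list.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}
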