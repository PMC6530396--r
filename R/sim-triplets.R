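#' @importFrom Biostrings GENETIC_CODE DNAStringSet readDNAStringSet
#'   writeXStringSet letterFrequency
NULL

.dupribo <- new.env(parent = emptyenv())

nuc_alphabet <- c("A", "C", "G", "T")

#' All 61 sense codons of the standard genetic code
#' @return Character vector of codons.
#' @keywords internal
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

is_stop_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  !is.na(aa) & aa == "*"
}

# JC69: evolve a nucleotide vector along a branch of b expected
# substitutions/site; a hit replaces the base with one of the other three.
jc_evolve <- function(nucs, b) {
  if (b < 0) stop("branch length must be >= 0")
  if (b == 0) return(nucs)
  p_change <- 0.75 * (1 - exp(-4 * b / 3))
  hit <- stats::runif(length(nucs)) < p_change
  if (any(hit)) {
    nucs[hit] <- vapply(nucs[hit], function(x)
      sample(setdiff(nuc_alphabet, x), 1), character(1))
  }
  nucs
}

#' Simulate a codon triplet alignment under Jukes-Cantor
#'
#' Draws a root coding sequence of `n_codons` codons uniformly from the 61
#' sense codons and evolves it independently along three branches — the two
#' paralogs and the outgroup ortholog of a star tree — under the JC69
#' nucleotide model with the given expected substitutions per site. Leaf
#' codons that become stop codons are re-evolved from the root codon along
#' the same branch so the alignment stays stop-free.
#'
#' @param b1,b2,b_out Branch lengths (expected substitutions/site) for
#'   paralog 1, paralog 2 and the outgroup.
#' @param n_codons Number of codons.
#' @param seed RNG seed.
#' @return A `triplet_alignment`: list with `seqs` (named character vector:
#'   paralog1, paralog2, outgroup) and `n_codons`.
#' @export
simulate_triplet_sequences <- function(b1, b2, b_out, n_codons, seed = 1L) {
  stopifnot(b1 >= 0, b2 >= 0, b_out >= 0, n_codons >= 1)
  set.seed(seed)
  root_codons <- sample(sense_codons(), n_codons, replace = TRUE)
  root <- unlist(strsplit(root_codons, ""))
  branches <- c(paralog1 = b1, paralog2 = b2, outgroup = b_out)
  seqs <- vapply(names(branches), function(nm) {
    leaf <- jc_evolve(root, branches[[nm]])
    cod <- apply(matrix(leaf, nrow = 3), 2, paste, collapse = "")
    bad <- which(is_stop_codon(cod))
    for (j in bad) {
      for (try in 1:200) {
        cand <- paste(jc_evolve(unlist(strsplit(root_codons[j], "")),
                                branches[[nm]]), collapse = "")
        if (!is_stop_codon(cand)) { cod[j] <- cand; break }
        if (try == 200) cod[j] <- root_codons[j]
      }
    }
    paste(cod, collapse = "")
  }, character(1))
  structure(list(seqs = seqs, n_codons = n_codons),
            class = "triplet_alignment")
}

#' Write / read a triplet alignment as FASTA
#'
#' @param triplet A `triplet_alignment`.
#' @param path FASTA file path.
#' @return `read_triplet_fasta` returns a `triplet_alignment` whose first
#'   two records are taken as the paralogs and the third as the outgroup.
#' @export
write_triplet_fasta <- function(triplet, path) {
  stopifnot(inherits(triplet, "triplet_alignment"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(triplet$seqs), path)
  invisible(path)
}

#' @rdname write_triplet_fasta
#' @export
read_triplet_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 3) stop("triplet FASTA must contain exactly 3 sequences: ", path)
  w <- unique(Biostrings::width(ss))
  if (length(w) != 1) stop("triplet sequences must be aligned (equal length)")
  if (w %% 3 != 0) stop("alignment length must be a multiple of 3")
  seqs <- stats::setNames(as.character(ss),
                          c("paralog1", "paralog2", "outgroup"))
  structure(list(seqs = seqs, n_codons = w / 3, ids = names(ss)),
            class = "triplet_alignment")
}
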