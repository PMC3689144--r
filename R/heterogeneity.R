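#' Count variable (segregating) nucleotide sites
#'
#' A column is variable when it holds two or more distinct non-missing
#' characters; `N` and `-` are ignored per column (pairwise deletion).
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return integer count S.
#' @export
variable_sites <- function(seqs) {
  m <- seq_char_matrix(seqs)
  sum(apply(m, 2, function(col) {
    u <- unique(col[!(col %in% c("N", "-"))])
    length(u) >= 2
  }))
}

#' Average nucleotide diversity (pi)
#'
#' Mean, over all unordered sequence pairs, of the proportion of differing
#' sites among sites where both sequences are non-missing (raw p-distance;
#' no multiple-hit correction).
#'
#' @param seqs character vector of >= 2 equal-length aligned sequences.
#' @return pi per site (multiply by 100 for the per-100-nt convention).
#' @export
nucleotide_diversity <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  m <- seq_char_matrix(seqs)
  ok <- !(m %in% c("N", "-"))
  dim(ok) <- dim(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    ncomp <- sum(comp)
    if (ncomp == 0)
      stop("sequences ", i, " and ", j, " share no comparable sites")
    tot <- tot + sum(m[i, comp] != m[j, comp]) / ncomp
  }
  tot / choose(n, 2)
}

#' Count variable amino acid residues
#'
#' Translates each sequence from `frame_offset` with the given NCBI genetic
#' code (trailing partial codon dropped; any codon containing a missing or
#' ambiguous character translates to missing), then counts variable residue
#' columns with the same rule as [variable_sites()].
#'
#' @param seqs character vector of equal-length aligned coding sequences.
#' @param frame_offset 0-based offset of the first complete codon.
#' @param genetic_code_id NCBI translation table id (default 11, bacterial).
#' @return integer count of variable amino acid positions.
#' @export
variable_amino_acids <- function(seqs, frame_offset = 0L,
                                 genetic_code_id = 11L) {
  if ((nchar(seqs[[1]]) - frame_offset) < 3)
    stop("alignment too short to hold one codon at this frame")
  code <- genetic_code(genetic_code_id)
  aa <- vapply(seqs, translate_frame, character(1),
               frame_offset = frame_offset, code = code)
  m <- seq_char_matrix(aa)
  sum(apply(m, 2, function(col) {
    u <- unique(col[col != "X"])
    length(u) >= 2
  }))
}

genetic_code <- function(id) {
  tbl <- Biostrings::getGeneticCode(as.character(id))
  if (is.null(tbl)) stop("invalid genetic_code_id: ", id)
  tbl
}

translate_frame <- function(seq, frame_offset, code) {
  s <- substr(seq, frame_offset + 1, nchar(seq))
  ncod <- nchar(s) %/% 3
  if (ncod == 0) return("")
  codons <- substring(s, 3 * (seq_len(ncod) - 1) + 1, 3 * seq_len(ncod))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons with N/- or other ambiguity -> missing
  paste(aa, collapse = "")
}

#' Per-locus heterogeneity summary
#'
#' Computes, for each locus alignment, the classic MLSA descriptors: aligned
#' length, number of alleles n_a, segregating sites S, average nucleotide
#' diversity per 100 sites, and the number of variable amino acid residues.
#'
#' @param alignments named list of per-locus aligned sequence vectors
#'   (elements as returned by [read_locus_alignment()]).
#' @param loci optional [locus_table()] supplying frame offsets and genetic
#'   codes; defaults to frame 0, code 11 for every locus.
#' @return data.frame with one row per locus.
#' @export
locus_summary <- function(alignments, loci = NULL) {
  nm <- names(alignments)
  if (is.null(loci)) loci <- locus_table(nm, vapply(alignments, function(s)
    nchar(s[[1]]), integer(1)))
  rows <- lapply(nm, function(lc) {
    seqs <- alignments[[lc]]
    info <- loci[loci$name == lc, ]
    data.frame(locus = lc,
               aligned_length = nchar(seqs[[1]]),
               n_a = length(unique(seqs)),
               S = variable_sites(seqs),
               Pi_per_100 = 100 * nucleotide_diversity(seqs),
               variable_aa = variable_amino_acids(
                 seqs, info$frame_offset, info$genetic_code_id),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

seq_char_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) stop("sequences differ in length")
  do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
}
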