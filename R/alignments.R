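#' Read a per-locus multiple sequence alignment from FASTA
#'
#' All records must be the same length (the input is an alignment, not raw
#' reads).  Sequences are uppercased; only the characters A, C, G, T, N and
#' the gap `-` are accepted.  `N` and `-` are treated as missing data by all
#' downstream statistics (pairwise deletion).
#'
#' @param path FASTA file.
#' @param locus_name optional name stored in the `"locus"` attribute.
#' @return named character vector of aligned sequences, in file order.
#' @export
read_locus_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1) stop("no records in ", path)
  if (anyDuplicated(names(ss)))
    stop("duplicate record id in ", path, ": ",
         names(ss)[duplicated(names(ss))][1])
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1)
    stop("alignment length mismatch in ", path, ": record '",
         names(ss)[which(w != w[1])[1]], "' has length ",
         w[which(w != w[1])[1]], ", expected ", w[1])
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid character in record '", names(seqs)[bad][1], "'")
  if (is.null(locus_name))
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  attr(seqs, "locus") <- locus_name
  seqs
}

#' Write aligned sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_alignment <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80)
  invisible(path)
}

#' Call alleles from an aligned set of sequences
#'
#' Each distinct aligned string is one allele; indices are assigned densely,
#' 1-based, in order of first appearance.  Exact string identity defines an
#' allele -- missing characters are not imputed, so two sequences differing
#' only at a gap or N position are distinct alleles.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (one per isolate).
#' @param locus_name locus label for the catalog.
#' @return list with `catalog` (an [allele_catalog()]) and `indices`
#'   (integer allele index per input sequence, named as the input).
#' @export
call_alleles <- function(seqs, locus_name = attr(seqs, "locus")) {
  if (length(seqs) == 0) stop("no sequences to call alleles from")
  if (length(unique(nchar(seqs))) != 1) stop("sequences differ in length")
  uniq <- unique(seqs)
  idx <- match(seqs, uniq)
  names(idx) <- names(seqs)
  list(catalog = allele_catalog(locus_name, uniq), indices = idx)
}

#' Construct an allele catalog
#'
#' A per-locus registry mapping dense 1-based allele indices to aligned
#' sequences, or -- when sequences are unavailable -- to a table of pairwise
#' nucleotide differences between alleles.
#'
#' @param locus_name locus label.
#' @param sequences character vector; element i is the sequence of allele i.
#'   May be NULL when only `distances` are known.
#' @param distances optional data.frame with columns `allele_a`, `allele_b`,
#'   `nt_diff` (sparse symmetric entries).
#' @return object of class `"allele_catalog"`.
#' @export
allele_catalog <- function(locus_name, sequences = NULL, distances = NULL) {
  if (!is.null(sequences)) {
    if (length(sequences) < 1) stop("empty allele catalog")
    if (length(unique(nchar(sequences))) != 1)
      stop("catalog sequences differ in length for locus ", locus_name)
    if (anyDuplicated(sequences))
      stop("duplicate allele sequences in catalog for locus ", locus_name)
    names(sequences) <- as.character(seq_along(sequences))
  }
  structure(list(locus = locus_name, sequences = sequences,
                 distances = distances,
                 aligned_length = if (!is.null(sequences))
                   nchar(sequences[[1]]) else NA_integer_),
            class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat(sprintf("Allele catalog '%s': %s alleles%s\n", x$locus,
              if (!is.null(x$sequences)) length(x$sequences)
              else "(distance-only)",
              if (!is.null(x$sequences))
                sprintf(", aligned length %d nt", x$aligned_length) else ""))
  invisible(x)
}

#' Number of alleles in a catalog
#' @param catalog an `allele_catalog`.
#' @return integer count.
#' @export
n_alleles <- function(catalog) {
  if (!is.null(catalog$sequences)) return(length(catalog$sequences))
  if (!is.null(catalog$distances))
    return(length(unique(c(catalog$distances$allele_a,
                           catalog$distances$allele_b))))
  NA_integer_
}

#' Nucleotide distance between two alleles
#'
#' Hamming distance over non-missing columns when the catalog carries
#' sequences; otherwise a lookup in the sparse allele-distance table.
#' Returns NA (unknown) when neither source resolves the pair.
#'
#' @param catalog an `allele_catalog`.
#' @param a,b 1-based allele indices.
#' @return integer nucleotide difference count, or NA.
#' @export
allele_nt_distance <- function(catalog, a, b) {
  if (a == b) return(0L)
  if (!is.null(catalog$sequences)) {
    nm <- names(catalog$sequences)
    if (!all(c(a, b) %in% nm))
      stop("allele index not in catalog for locus ", catalog$locus)
    sa <- catalog$sequences[[as.character(a)]]
    sb <- catalog$sequences[[as.character(b)]]
    d <- hamming_nt(sa, sb)
    if (d == 0L)
      warning("alleles ", a, " and ", b, " of locus ", catalog$locus,
              " are identical at all comparable sites")
    return(d)
  }
  if (!is.null(catalog$distances)) {
    dd <- catalog$distances
    hit <- (dd$allele_a == a & dd$allele_b == b) |
      (dd$allele_a == b & dd$allele_b == a)
    if (any(hit)) return(as.integer(dd$nt_diff[which(hit)[1]]))
  }
  NA_integer_
}

# Hamming distance with pairwise deletion of N/- positions.
hamming_nt <- function(sa, sb) {
  ca <- strsplit(sa, "", fixed = TRUE)[[1]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1]]
  ok <- !(ca %in% c("N", "-")) & !(cb %in% c("N", "-"))
  sum(ca[ok] != cb[ok])
}

#' Concatenate per-locus allele sequences into one string per isolate
#'
#' @param x an `isolate_table`.
#' @param catalogs named list of `allele_catalog`, one per locus of `x`.
#' @return named character vector of concatenated sequences, one per
#'   isolate, in the recorded locus order.
#' @export
concatenate_loci <- function(x, catalogs) {
  loci <- loci_of(x)
  miss <- setdiff(loci, names(catalogs))
  if (length(miss)) stop("no catalog for locus ", miss[1])
  prof <- profile_matrix(x)
  parts <- lapply(loci, function(lc) {
    cat_l <- catalogs[[lc]]
    if (is.null(cat_l$sequences))
      stop("catalog for locus ", lc, " has no sequences")
    idx <- prof[, lc]
    if (any(idx > length(cat_l$sequences)))
      stop("allele index ", max(idx), " not in catalog for locus ", lc)
    unname(cat_l$sequences[idx])
  })
  out <- do.call(paste0, parts)
  names(out) <- x$isolate_id
  out
}
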