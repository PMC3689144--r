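#' Enumerate single-locus-variant (SLV) sequence-type pairs
#'
#' Scans all unordered ST pairs and keeps those whose allelic profiles
#' differ at exactly one locus.  `same_spring` is TRUE when the two STs'
#' spring provenance sets intersect.
#'
#' @param stt a `sequence_type_table` (see [assign_sequence_types()]).
#' @return data.frame with columns st_a, st_b, variant_locus, allele_a,
#'   allele_b, same_spring; zero rows when no SLVs exist.
#' @export
find_slvs <- function(stt) {
  if (nrow(stt) < 2)
    return(data.frame(st_a = integer(), st_b = integer(),
                      variant_locus = character(), allele_a = integer(),
                      allele_b = integer(), same_spring = logical()))
  prof <- profile_matrix(stt)
  loci <- loci_of(stt)
  springs <- strsplit(stt$springs, ";", fixed = TRUE)
  out <- list()
  n <- nrow(prof)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- which(prof[i, ] != prof[j, ])
    if (length(d) == 1) {
      out[[length(out) + 1]] <- data.frame(
        st_a = stt$st[i], st_b = stt$st[j],
        variant_locus = loci[d],
        allele_a = prof[i, d], allele_b = prof[j, d],
        same_spring = length(intersect(springs[[i]], springs[[j]])) > 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(find_slvs(stt[0, , drop = FALSE]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify an SLV as recombination (R) or mutation (M)
#'
#' Feil-style binning: a variant differing by multiple nucleotides, or a
#' single-nucleotide variant whose alleles are both observed repeatedly in
#' the dataset, is attributed to homologous recombination; a
#' single-nucleotide variant in which at least one of the two alleles is
#' confined to a single ST (the putative novel variant) is attributed to
#' point mutation.  "Observed repeatedly" is evaluated at the ST level: an
#' allele carried by one ST counts once no matter how many isolates hold
#' that ST.
#'
#' @param nt_diff nucleotide difference count between the two alleles (NA =
#'   unknown).
#' @param n_st_a,n_st_b number of distinct STs carrying allele a (resp. b)
#'   at the variant locus.
#' @return `"R"`, `"M"` or `"UNKNOWN"`.
#' @export
classify_slv <- function(nt_diff, n_st_a, n_st_b) {
  if (is.na(nt_diff)) return("UNKNOWN")
  if (nt_diff > 1) return("R")
  if (n_st_a >= 2 && n_st_b >= 2) return("R")
  "M"
}

#' SLV report with recombination/mutation tallies
#'
#' Enumerates SLV pairs, attaches the nucleotide distance between the two
#' variant alleles (from sequence catalogs or sparse allele-distance
#' tables), classifies each pair with [classify_slv()], and tallies the
#' calls.
#'
#' @param stt a `sequence_type_table`.
#' @param catalogs named list of `allele_catalog` (per locus); catalogs may
#'   carry sequences or distance tables (see [allele_catalog()]).
#' @return object of class `"slv_report"`: list with `records` (data.frame
#'   sorted by st_a, st_b, with nt_diff and call columns) and `tally`
#'   (named counts of R, M, UNKNOWN).
#' @export
slv_report <- function(stt, catalogs = NULL) {
  rec <- find_slvs(stt)
  prof <- profile_matrix(stt)
  if (nrow(rec) > 0) {
    rec$nt_diff <- vapply(seq_len(nrow(rec)), function(k) {
      lc <- rec$variant_locus[k]
      if (is.null(catalogs) || is.null(catalogs[[lc]])) return(NA_integer_)
      allele_nt_distance(catalogs[[lc]], rec$allele_a[k], rec$allele_b[k])
    }, integer(1))
    rec$call <- vapply(seq_len(nrow(rec)), function(k) {
      lc <- rec$variant_locus[k]
      classify_slv(rec$nt_diff[k],
                   n_st_a = sum(prof[, lc] == rec$allele_a[k]),
                   n_st_b = sum(prof[, lc] == rec$allele_b[k]))
    }, character(1))
    rec <- rec[order(rec$st_a, rec$st_b), ]
    rownames(rec) <- NULL
  } else {
    rec$nt_diff <- integer(0)
    rec$call <- character(0)
  }
  tally <- c(R = sum(rec$call == "R"), M = sum(rec$call == "M"),
             UNKNOWN = sum(rec$call == "UNKNOWN"))
  structure(list(records = rec, tally = tally), class = "slv_report")
}

#' @export
print.slv_report <- function(x, ...) {
  cat(sprintf("Single-locus variants: %d pairs (%d same-spring)\n",
              nrow(x$records), sum(x$records$same_spring)))
  if (nrow(x$records)) print.data.frame(x$records)
  cat(sprintf("Calls: R = %d, M = %d, unknown = %d\n",
              x$tally[["R"]], x$tally[["M"]], x$tally[["UNKNOWN"]]))
  invisible(x)
}
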