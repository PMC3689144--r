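#' Allele frequencies at one locus
#'
#' Frequencies are computed over isolates by default; with `st_mode = TRUE`
#' each distinct sequence type contributes once instead (deduplicated
#' profiles), the contrast used when separating clonal expansion from the
#' underlying allele pool.
#'
#' @param x an `isolate_table`.
#' @param locus locus name.
#' @param subset optional logical or integer index selecting isolates.
#' @param st_mode count each sequence type once instead of each isolate.
#' @return named numeric vector of frequencies (names = allele indices),
#'   summing to 1.
#' @export
allele_frequencies <- function(x, locus, subset = NULL, st_mode = FALSE) {
  if (!locus %in% loci_of(x)) stop("unknown locus: ", locus)
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  if (nrow(x) == 0) stop("empty isolate subset")
  prof <- profile_matrix(x)
  if (st_mode)
    prof <- prof[!duplicated(apply(prof, 1, paste, collapse = ";")), ,
                 drop = FALSE]
  tab <- table(prof[, locus])
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Nei-type unbiased genetic diversity H
#'
#' H = (n/(n-1)) (1 - sum p_i^2): the probability that two isolates sampled
#' without replacement carry different alleles.  Clamped to [0, 1]; NA when
#' n < 2.
#'
#' @param p numeric vector of allele frequencies (summing to 1).
#' @param n number of isolates the frequencies were computed from.
#' @return H in [0, 1], or NA.
#' @export
genetic_diversity_H <- function(p, n) {
  if (n < 2) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  h <- (n / (n - 1)) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

#' Per-locus diversity summary for a population and its subsets
#'
#' One row per (subset, locus) with the number of isolates, number of
#' alleles and unbiased diversity H, plus a mean-H row per subset (locus
#' `"(mean)"`, unweighted mean over loci).  `partition = NULL` analyses the
#' whole table as one subset labelled `"all"`.
#'
#' @param x an `isolate_table`.
#' @param partition optional character vector (length `nrow(x)`) of subset
#'   labels, e.g. `x$spring`.
#' @param st_mode forward to [allele_frequencies()].
#' @return data.frame with columns subset, locus, n, n_a, H.
#' @export
diversity_summary <- function(x, partition = NULL, st_mode = FALSE) {
  if (is.null(partition)) partition <- rep("all", nrow(x))
  stopifnot(length(partition) == nrow(x))
  loci <- loci_of(x)
  out <- NULL
  for (g in unique(partition)) {
    sel <- which(partition == g)
    rows <- lapply(loci, function(lc) {
      p <- allele_frequencies(x, lc, subset = sel, st_mode = st_mode)
      n <- if (st_mode) {
        prof <- profile_matrix(x[sel, , drop = FALSE])
        sum(!duplicated(apply(prof, 1, paste, collapse = ";")))
      } else length(sel)
      data.frame(subset = g, locus = lc, n = n, n_a = length(p),
                 H = genetic_diversity_H(p, n), stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    mean_row <- data.frame(subset = g, locus = "(mean)", n = rows$n[1],
                           n_a = NA_integer_, H = mean(rows$H),
                           stringsAsFactors = FALSE)
    out <- rbind(out, rows, mean_row)
  }
  rownames(out) <- NULL
  out
}
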