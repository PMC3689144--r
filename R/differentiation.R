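#' Pairwise nucleotide differences between concatenated sequences
#'
#' Counts differing positions over sites where both sequences are
#' non-missing (pairwise deletion of `N` and `-`); with
#' `p_distance = TRUE` each count is divided by the number of compared
#' sites.
#'
#' @param seqs named character vector of equal-length sequences.
#' @param p_distance return proportions instead of counts.
#' @return a `stats::dist` object with the sequence names as labels.
#' @export
pairwise_nt_differences <- function(seqs, p_distance = FALSE) {
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  m <- seq_char_matrix(seqs)
  ok <- !(m %in% c("N", "-"))
  dim(ok) <- dim(m)
  mat <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nd <- sum(m[i, comp] != m[j, comp])
    mat[i, j] <- mat[j, i] <- if (p_distance) nd / sum(comp) else nd
  }
  stats::as.dist(mat)
}

#' AMOVA-based pairwise F_ST between two subpopulations
#'
#' Excoffier-style haplotypic AMOVA on a matrix of pairwise sequence
#' differences, treating each difference count as a squared Euclidean
#' distance.  With SSD_total the total sum of squared deviations and
#' SSD_within the sum within the two groups, the variance components are
#' sigma2_b = SSD_within / (N - 2) and sigma2_a = (SSD_among / 1 -
#' sigma2_b) / n', where n' = (N - sum(n_p^2)/N) / (P - 1) is the average
#' subsample size; F_ST = sigma2_a / (sigma2_a + sigma2_b).  Negative
#' estimates are reported as computed.
#'
#' @param d a `dist` of pairwise differences over all individuals.
#' @param partition character vector of subpopulation labels, one per
#'   individual, aligned with the labels of `d`.
#' @param a,b the two subpopulation labels to compare.
#' @return F_ST estimate (numeric scalar; NA when either subset has fewer
#'   than two members).
#' @export
pairwise_fst <- function(d, partition, a, b) {
  dm <- as.matrix(d)
  sel <- partition %in% c(a, b)
  dm <- dm[sel, sel, drop = FALSE]
  grp <- partition[sel]
  amova_fst(dm, grp == a)
}

# core two-group AMOVA from a square difference matrix
amova_fst <- function(dm, in_a) {
  na <- sum(in_a); nb <- sum(!in_a)
  if (na < 2 || nb < 2) return(NA_real_)
  N <- na + nb
  sq <- dm  # difference counts play the role of squared distances
  ssd_tot <- sum(sq[upper.tri(sq)]) / N
  ssd_a <- sum(sq[in_a, in_a][upper.tri(diag(na))]) / na
  ssd_b <- sum(sq[!in_a, !in_a][upper.tri(diag(nb))]) / nb
  ssd_within <- ssd_a + ssd_b
  ssd_among <- ssd_tot - ssd_within
  sigma2_b <- ssd_within / (N - 2)
  n_prime <- (N - (na^2 + nb^2) / N)  # / (P - 1), P = 2
  sigma2_a <- (ssd_among / 1 - sigma2_b) / n_prime
  if (sigma2_a + sigma2_b == 0) return(0)
  sigma2_a / (sigma2_a + sigma2_b)
}

#' Permutation significance for pairwise F_ST
#'
#' The null is built by randomly reassigning individuals between the two
#' subpopulations, preserving subset sizes; P is add-one corrected.
#'
#' @param d a `dist` of pairwise differences.
#' @param partition subpopulation labels aligned with `d`.
#' @param a,b labels of the pair to test.
#' @param permutations number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `F_ST`, `P`, `permutations`.
#' @export
fst_significance <- function(d, partition, a, b, permutations = 1000L,
                             seed = NULL) {
  if (permutations < 100) stop("permutations must be >= 100")
  dm <- as.matrix(d)
  sel <- partition %in% c(a, b)
  dm <- dm[sel, sel, drop = FALSE]
  grp <- partition[sel]
  obs <- amova_fst(dm, grp == a)
  if (is.na(obs)) return(list(F_ST = NA_real_, P = NA_real_,
                              permutations = permutations))
  if (!is.null(seed)) set.seed(seed)
  na <- sum(grp == a); n <- length(grp)
  null <- vapply(seq_len(permutations), function(k) {
    ia <- logical(n); ia[sample.int(n, na)] <- TRUE
    amova_fst(dm, ia)
  }, numeric(1))
  P <- (sum(null >= obs, na.rm = TRUE) + 1) / (permutations + 1)
  list(F_ST = obs, P = P, permutations = as.integer(permutations))
}

#' All pairwise F_ST values between subpopulations
#'
#' @param d a `dist` of pairwise differences over all individuals.
#' @param partition subpopulation labels aligned with `d`.
#' @param permutations if > 0, attach permutation P values.
#' @param seed RNG seed.
#' @return object of class `"fst_matrix"`: list with `fst` (lower-triangle
#'   matrix), `P` (matching matrix or NULL) and `levels`.
#' @export
fst_matrix <- function(d, partition, permutations = 0L, seed = NULL) {
  lev <- unique(partition)
  k <- length(lev)
  fst <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  pv <- if (permutations > 0) fst else NULL
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (permutations > 0) {
      r <- fst_significance(d, partition, lev[i], lev[j],
                            permutations = permutations, seed = NULL)
      fst[j, i] <- r$F_ST
      pv[j, i] <- r$P
    } else {
      fst[j, i] <- pairwise_fst(d, partition, lev[i], lev[j])
    }
  }
  structure(list(fst = fst, P = pv, levels = lev,
                 permutations = as.integer(permutations)),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise F_ST (AMOVA, pairwise sequence differences)\n")
  print(round(x$fst, digits), na.print = "")
  if (!is.null(x$P)) {
    cat(sprintf("Permutation P values (%d permutations)\n", x$permutations))
    print(round(x$P, 4), na.print = "")
  }
  invisible(x)
}

#' Spearman Mantel test for isolation by distance
#'
#' Correlates two distance matrices (typically genetic p-distance and
#' geographic separation) by Spearman's rank correlation of their condensed
#' upper-triangle vectors, with significance from random permutation of the
#' labels of one matrix.  Significance is reported as a percentage, add-one
#' corrected, matching the convention of RELATE-style matrix-correlation
#' tests.
#'
#' @param d_gen,d_geo `dist` objects (or square matrices) on the same
#'   labels in the same order; n >= 4.
#' @param permutations label permutations for the null.
#' @param seed RNG seed.
#' @return object of class `"mantel_result"`: list with `rho`,
#'   `significance_percent`, `permutations`, `seed`.
#' @export
mantel_spearman <- function(d_gen, d_geo, permutations = 999L, seed = NULL) {
  mg <- as.matrix(d_gen)
  mh <- as.matrix(d_geo)
  if (!identical(dim(mg), dim(mh)))
    stop("distance matrices differ in size")
  if (!is.null(rownames(mg)) && !is.null(rownames(mh)) &&
      !identical(rownames(mg), rownames(mh)))
    stop("distance matrix labels do not match")
  n <- nrow(mg)
  if (n < 4) stop("need at least 4 objects for a Mantel test")
  vg <- mg[lower.tri(mg)]
  vh <- mh[lower.tri(mh)]
  if (stats::sd(vg) == 0 || stats::sd(vh) == 0) {
    warning("a distance matrix is constant: rho undefined")
    return(structure(list(rho = NA_real_, significance_percent = NA_real_,
                          permutations = as.integer(permutations),
                          seed = seed), class = "mantel_result"))
  }
  rho <- stats::cor(vg, vh, method = "spearman")
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(permutations), function(k) {
    p <- sample.int(n)
    mp <- mh[p, p]
    stats::cor(vg, mp[lower.tri(mp)], method = "spearman")
  }, numeric(1))
  sig <- 100 * (sum(null >= rho) + 1) / (permutations + 1)
  structure(list(rho = rho, significance_percent = sig,
                 permutations = as.integer(permutations), seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Spearman Mantel test: rho = %.3f, significance = %.2f%% (%d permutations)\n",
              x$rho, x$significance_percent, x$permutations))
  invisible(x)
}
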