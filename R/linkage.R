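#' Pairwise locus-mismatch distribution
#'
#' For every unordered pair of profiles, the number of loci at which the two
#' allele indices differ.  This is the distribution whose variance drives
#' the index of association.
#'
#' @param profiles integer matrix, rows = isolates, columns = loci.
#' @return integer vector of length choose(n, 2), in the order of
#'   `utils::combn(n, 2)` / `stats::dist` (column-major lower triangle).
#' @export
mismatch_distribution <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least two profiles")
  if (anyNA(profiles)) stop("profiles contain missing allele indices")
  K <- integer(n * (n - 1) / 2)
  for (j in seq_len(ncol(profiles))) {
    a <- profiles[, j]
    K <- K + as.integer(as.vector(stats::dist(a)) > 0)
  }
  K
}

#' Standardized index of association
#'
#' Tests the null hypothesis of linkage equilibrium (free recombination)
#' among loci.  With K the pairwise locus-mismatch counts, V_D their sample
#' variance (denominator choose(n,2) - 1), and V_E = sum_j h_j (1 - h_j) the
#' variance expected under independence -- h_j being the unbiased per-locus
#' diversity (n/(n-1))(1 - sum p^2) -- the classical index is
#' I_A = V_D/V_E - 1 and the standardized index I_SA = I_A / (l - 1).
#' I_SA is 0 in expectation under free recombination and positive under
#' linkage disequilibrium.
#'
#' The variance conventions (sample-variance V_D, unbiased h_j) are locked
#' by a worked 7-isolate example in the test-suite; the three biased
#' alternatives give detectably different values and are rejected.
#'
#' @param profiles integer matrix of allelic profiles (rows = isolates), or
#'   an `isolate_table`.
#' @param label subset label carried into the result.
#' @param resamples if > 0, a Monte-Carlo P value is attached (see
#'   [i_sa_significance()]).
#' @param seed RNG seed for the resampling null.
#' @param min_n smallest n for which a value is reported; below it the
#'   result is NA (configurable; some published analyses report NA for very
#'   small ST sets).
#' @return object of class `"linkage_result"`: a list with n, l, K, V_D,
#'   V_E, I_A, I_SA, P, resamples, seed, label.
#' @export
i_sa <- function(profiles, label = "all", resamples = 0L, seed = NULL,
                 min_n = 3L) {
  if (inherits(profiles, "isolate_table")) profiles <- profile_matrix(profiles)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  l <- ncol(profiles)
  res <- structure(list(label = label, n = n, l = l, K = NULL,
                        V_D = NA_real_, V_E = NA_real_, I_A = NA_real_,
                        I_SA = NA_real_, P = NA_real_,
                        resamples = as.integer(resamples), seed = seed),
                   class = "linkage_result")
  if (n < max(2L, min_n)) return(res)
  K <- mismatch_distribution(profiles)
  res$K <- K
  res$V_D <- stats::var(K)  # denominator choose(n,2) - 1
  h <- apply(profiles, 2, function(a) {
    p <- as.numeric(table(a)) / n
    (n / (n - 1)) * (1 - sum(p^2))
  })
  res$V_E <- sum(h * (1 - h))
  if (res$V_E == 0) {
    warning("all loci monomorphic: index of association undefined")
    return(res)
  }
  res$I_A <- res$V_D / res$V_E - 1
  res$I_SA <- res$I_A / (l - 1)
  if (resamples > 0)
    res$P <- i_sa_significance(profiles, resamples = resamples, seed = seed,
                               min_n = min_n)$P
  res
}

#' Monte-Carlo significance for the index of association
#'
#' The null distribution is generated by independently permuting the allele
#' column of each locus across isolates, which preserves allele frequencies
#' while destroying between-locus association.  P is add-one corrected:
#' (#\{I_SA_perm >= I_SA_obs\} + 1) / (resamples + 1).
#'
#' @param profiles integer matrix of allelic profiles.
#' @param resamples number of permutations (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param min_n forwarded to [i_sa()].
#' @return list with `P`, `I_SA_obs`, `null` (vector of permuted I_SA).
#' @export
i_sa_significance <- function(profiles, resamples = 1000L, seed = NULL,
                              min_n = 3L) {
  if (inherits(profiles, "isolate_table")) profiles <- profile_matrix(profiles)
  profiles <- as.matrix(profiles)
  if (resamples < 100) stop("resamples must be >= 100")
  obs <- i_sa(profiles, resamples = 0L, min_n = min_n)$I_SA
  if (is.na(obs)) return(list(P = NA_real_, I_SA_obs = NA_real_, null = NULL))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- nrow(profiles)
  null <- vapply(seq_len(resamples), function(k) {
    perm <- apply(profiles, 2, sample, size = n)
    i_sa(perm, resamples = 0L, min_n = min_n)$I_SA
  }, numeric(1))
  P <- (sum(null >= obs, na.rm = TRUE) + 1) / (resamples + 1)
  list(P = P, I_SA_obs = obs, null = null)
}

#' Isolate-level versus ST-level linkage: the epidemic-structure contrast
#'
#' Runs [i_sa()] twice, on all isolates and on the deduplicated set of
#' unique sequence-type profiles.  A marked drop from the isolate-level to
#' the ST-level index is the signature of an "epidemic" population
#' structure: a recombining background from which one or a few clones have
#' recently expanded.
#'
#' @param x an `isolate_table`.
#' @param resamples,seed forwarded to [i_sa()].
#' @return object of class `"epidemic_contrast"`: list with elements
#'   `isolates` and `unique_sts`, both `linkage_result`.
#' @export
epidemic_contrast <- function(x, resamples = 0L, seed = NULL) {
  prof <- profile_matrix(x)
  uniq <- prof[!duplicated(apply(prof, 1, paste, collapse = ";")), ,
               drop = FALSE]
  structure(list(
    isolates = i_sa(prof, label = "all isolates", resamples = resamples,
                    seed = seed),
    unique_sts = i_sa(uniq, label = "unique STs", resamples = resamples,
                      seed = if (is.null(seed)) NULL else seed + 1L)),
    class = "epidemic_contrast")
}

#' @export
print.linkage_result <- function(x, digits = 3, ...) {
  cat(sprintf("Index of association (%s): n = %d profiles, %d loci\n",
              x$label, x$n, x$l))
  if (is.na(x$I_SA)) {
    cat("  I_SA = NA\n")
  } else {
    cat(sprintf("  V_D = %.4f  V_E = %.4f  I_A = %.4f  I_SA = %.*f\n",
                x$V_D, x$V_E, x$I_A, digits, x$I_SA))
    if (!is.na(x$P))
      cat(sprintf("  P = %.4g (%d resamples)\n", x$P, x$resamples))
  }
  invisible(x)
}

#' @export
print.epidemic_contrast <- function(x, ...) {
  print(x$isolates)
  print(x$unique_sts)
  if (!is.na(x$isolates$I_SA) && !is.na(x$unique_sts$I_SA)) {
    cat(sprintf("Drop (isolate-level minus ST-level): %.3f\n",
                x$isolates$I_SA - x$unique_sts$I_SA))
  }
  invisible(x)
}
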